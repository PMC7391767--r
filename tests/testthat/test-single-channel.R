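test_that("detect_levels on clean and noisy two-level traces", {
  # noise-free two-level trace
  x <- rep(c(0, 1), each = 500)
  lev <- detect_levels(x)
  expect_equal(lev$n_levels, 2L)
  expect_lt(abs(lev$baseline_mean - 0), 0.01)
  expect_lt(abs(lev$open_mean - 1), 0.01)
  expect_lt(abs(lev$unitary_current - 1), 0.02)

  # synthetic trace with realistic noise and many events
  tr <- simulate_two_state_trace(50, 12.5, 50, 10000, open_current = 1,
                                 noise_sd = 0.1, filter_cutoff = 2900,
                                 seed = 21)
  expect_gt(nrow(tr$true_events), 500)
  lev2 <- detect_levels(tr$samples)
  expect_lt(abs(lev2$unitary_current - 1), 0.05)

  # conductance: i/V in pS (0.8 pA at +80 mV -> 10 pS)
  g <- detect_levels(c(rep(0, 500), rep(0.8, 500)), voltage = 80)
  expect_equal(g$conductance_pS, 10, tolerance = 0.2)

  # channel that never opens: one level, undefined unitary current
  set.seed(22)
  lone <- detect_levels(rnorm(5000, 0, 0.1))
  expect_equal(lone$n_levels, 1L)
  expect_true(is.na(lone$unitary_current))
})

test_that("idealization recovers noise-free renderings exactly", {
  # constant baseline -> single closed event
  rec0 <- idealize_half_amplitude(rep(0, 1000), 0, 1, dead_time = 0,
                                  sampling_rate = 1000)
  expect_equal(nrow(rec0$events), 1)
  expect_equal(rec0$events$state, "closed")
  expect_equal(rec0$events$duration, 1)

  # ground-truth event lists with all dwells >= 2x dead time
  set.seed(501)
  for (rep_i in 1:10) {
    ev <- draw_event_list(50, 12.5, 40, min_dwell = 2 * 0.32e-3)
    dur <- sum(ev$duration)
    x <- render_truth(ev, 10000, dur)
    rec <- idealize_half_amplitude(x, 0, 1, dead_time = 0.32e-3,
                                   sampling_rate = 10000)
    expect_equal(nrow(rec$events), nrow(ev))
    expect_equal(rec$events$state, ev$state)
    err <- abs(rec$events$duration - ev$duration)
    expect_true(all(err[!rec$events$edge] <= 1 / 10000 + 1e-12))
    expect_true(all(err[rec$events$edge] <= 2 / 10000 + 1e-12))
  }
})

test_that("dead time absorbs short events and is monotone", {
  # one 0.2 ms opening between long closures, 10 kHz sampling
  x <- c(rep(0, 500), rep(1, 2), rep(0, 500))
  rec_no_dt <- idealize_half_amplitude(x, 0, 1, dead_time = 0,
                                       sampling_rate = 10000)
  rec_dt <- idealize_half_amplitude(x, 0, 1, dead_time = 0.32e-3,
                                    sampling_rate = 10000)
  expect_equal(nrow(rec_no_dt$events), 3)
  expect_equal(nrow(rec_dt$events), nrow(rec_no_dt$events) - 2)
  expect_equal(rec_dt$events$state, "closed")
  # total duration is conserved by merging
  expect_equal(sum(rec_dt$events$duration), length(x) / 10000,
               tolerance = 1e-12)

  # event count non-increasing in dead time
  tr <- simulate_two_state_trace(80, 40, 20, 10000, noise_sd = 0.12,
                                 filter_cutoff = 2900, seed = 31)
  counts <- vapply(c(0, 0.1e-3, 0.32e-3, 1e-3, 3e-3), function(dt)
    nrow(idealize_half_amplitude(tr$samples, 0, 1, dead_time = dt,
                                 sampling_rate = 10000)$events),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(idealize_half_amplitude(x, 0, 1, dead_time = 0.05e-3,
                                         sampling_rate = 10000),
                 "sample period")
})

test_that("idealization is idempotent", {
  tr <- simulate_two_state_trace(50, 12.5, 10, 10000, noise_sd = 0.12,
                                 filter_cutoff = 2900, seed = 41)
  rec <- idealize_half_amplitude(tr$samples, 0, 1, dead_time = 0.32e-3,
                                 sampling_rate = 10000)
  again <- idealize_half_amplitude(render_events(rec), 0, 1,
                                   dead_time = 0.32e-3,
                                   sampling_rate = rec$sampling_rate)
  expect_equal(nrow(again$events), nrow(rec$events))
  expect_equal(again$events$state, rec$events$state)
  # boundaries that land exactly on sample instants may requantize by one
  # sample under floating-point comparison
  expect_true(all(abs(again$events$duration - rec$events$duration) <=
                    1 / rec$sampling_rate + 1e-12))
})

test_that("ties at threshold keep the previous state", {
  # samples exactly at 0.5 between excursions
  x <- c(0, 0, 1, 1, 0.5, 0.5, 0, 0)
  rec <- idealize_half_amplitude(x, 0, 1, dead_time = 0, sampling_rate = 1000)
  # the tied run extends the preceding open event
  expect_equal(rec$events$state, c("closed", "open", "closed"))
  expect_equal(rec$events$duration, c(2, 4, 2) / 1000, tolerance = 1e-12)
  # leading tie defaults to closed
  rec2 <- idealize_half_amplitude(c(0.5, 0, 1, 1), 0, 1, dead_time = 0,
                                  sampling_rate = 1000)
  expect_equal(rec2$events$state[1], "closed")
})

test_that("rates are exponential MLEs with correct hand values", {
  ev <- data.frame(state = c("open", "closed", "open", "closed", "open",
                             "closed", "open"),
                   duration = c(0.5, 0.010, 0.020, 0.030, 0.020, 0.020,
                                0.5))
  ev$start <- c(0, cumsum(ev$duration)[-nrow(ev)])
  ev$edge <- c(TRUE, rep(FALSE, 5), TRUE)
  rec <- structure(list(events = ev, dead_time = 0,
                        total_duration = sum(ev$duration),
                        sampling_rate = 1e4),
                   class = "idealized_record")
  kr <- estimate_rates(rec)
  # closed dwells {10, 30, 20 ms} -> 1/mean = 50/s
  expect_equal(kr$opening_rate, 50, tolerance = 1e-12)
  expect_equal(kr$closing_rate, 1 / 0.020, tolerance = 1e-12)
  expect_equal(kr$k_eq, kr$opening_rate / kr$closing_rate, tolerance = 1e-12)
  expect_equal(kr$se_opening, 50 / sqrt(3), tolerance = 1e-12)
  expect_equal(kr$n_closed_events, 3L)
})

test_that("rate and Po recovery from a simulated long trace", {
  tr <- simulate_two_state_trace(50, 12.5, 100, 10000, noise_sd = 0.15,
                                 filter_cutoff = 2900, seed = 77)
  expect_gt(nrow(tr$true_events), 2000)
  lev <- detect_levels(tr$samples)
  rec <- idealize_half_amplitude(tr$samples, lev$baseline_mean,
                                 lev$open_mean, dead_time = 0.32e-3,
                                 sampling_rate = 10000)
  kr <- estimate_rates(rec)
  expect_lt(abs(kr$opening_rate - 50) / 50, 0.1)
  expect_lt(abs(kr$closing_rate - 12.5) / 12.5, 0.1)
  po <- open_probability(rec)
  se <- sqrt(0.8 * 0.2 / kr$n_open_events)
  expect_lt(abs(po - 0.8), 3 * se + 0.01)
  # Po from events vs the trace's true open fraction
  ev <- tr$true_events
  true_po <- sum(ev$duration[ev$state == "open"]) / sum(ev$duration)
  expect_lt(abs(po - true_po), 0.02)
})

test_that("open_probability degenerate and simple cases", {
  all_open <- structure(list(
    events = data.frame(state = "open", start = 0, duration = 2,
                        edge = TRUE),
    total_duration = 2), class = "idealized_record")
  expect_equal(open_probability(all_open), 1)
  alt <- structure(list(
    events = data.frame(state = c("closed", "open"), start = c(0, 1),
                        duration = c(1, 1), edge = c(TRUE, TRUE)),
    total_duration = 2), class = "idealized_record")
  expect_equal(open_probability(alt), 0.5)
})

test_that("Bronsted fit: exact slopes, limits, and rejection", {
  for (phi in c(0, 0.25, 0.5, 0.75, 1)) {
    s <- simulate_mutant_series(50, 12.5, phi, c(-0.6, -0.3, 0, 0.3))
    pr <- fit_bronsted(s)
    expect_equal(pr$phi, phi, tolerance = 1e-12)
    expect_gt(pr$r_squared, 1 - 1e-10)
  }
  # identical closing rates -> Phi exactly 1; identical opening -> 0
  s1 <- data.frame(k_eq = c(1, 2, 4), opening_rate = c(10, 20, 40))
  expect_equal(fit_bronsted(s1)$phi, 1, tolerance = 1e-12)
  s0 <- data.frame(k_eq = c(1, 2, 4), opening_rate = c(10, 10, 10))
  expect_equal(fit_bronsted(s0)$phi, 0, tolerance = 1e-12)
  expect_error(fit_bronsted(s1[1:2, ]), ">= 3")
  expect_error(fit_bronsted(data.frame(k_eq = c(1, 1, 1),
                                       opening_rate = c(1, 2, 3))),
               "degenerate")
  # agrees with the closed-form OLS slope on a noisy series
  set.seed(5)
  pts <- data.frame(k_eq = 10^runif(5, -1, 1),
                    opening_rate = 10^runif(5, 0, 2))
  expect_equal(fit_bronsted(pts)$phi,
               ols_slope(log10(pts$k_eq), log10(pts$opening_rate)),
               tolerance = 1e-12)
})

test_that("Phi recovery from trace-estimated rates is unbiased-ish", {
  # moderate-size repeats: rates re-estimated from simulated recordings
  phis <- numeric(8)
  for (k in seq_along(phis)) {
    s <- simulate_mutant_series(50, 12.5, 0.7, c(-0.6, -0.3, 0, 0.3),
                                seed = k)
    rates <- lapply(seq_len(nrow(s)), function(i) {
      tr <- simulate_two_state_trace(s$opening_rate[i], s$closing_rate[i],
                                     duration = 30, sampling_rate = 10000,
                                     noise_sd = 0.15, filter_cutoff = 2900,
                                     seed = 1000 * k + i)
      rec <- idealize_half_amplitude(tr$samples, 0, 1, dead_time = 0.32e-3,
                                     sampling_rate = 10000)
      kr <- estimate_rates(rec)
      data.frame(k_eq = kr$k_eq, opening_rate = kr$opening_rate)
    })
    phis[k] <- fit_bronsted(do.call(rbind, rates))$phi
  }
  expect_lt(abs(mean(phis) - 0.7), 2 * sd(phis) / sqrt(length(phis)) + 0.05)
  expect_true(all(abs(phis - 0.7) < 0.2))
})
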