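test_that("two-state trace: absorbing closed state gives one flat event", {
  tr <- simulate_two_state_trace(0, 20, duration = 1, sampling_rate = 1000,
                                 noise_sd = 0, filter_cutoff = NULL,
                                 seed = 1)
  expect_equal(nrow(tr$true_events), 1)
  expect_equal(tr$true_events$state, "closed")
  expect_equal(tr$true_events$duration, 1)
  expect_true(all(tr$samples == 0))
})

test_that("two-state trace: event list alternates and tiles the duration", {
  for (seed in 1:5) {
    tr <- simulate_two_state_trace(50, 12.5, duration = 10,
                                   sampling_rate = 5000, noise_sd = 0,
                                   filter_cutoff = NULL, seed = seed)
    ev <- tr$true_events
    expect_true(all(ev$state[-1] != ev$state[-nrow(ev)]))
    expect_equal(sum(ev$duration), 10, tolerance = 1e-12)
    expect_equal(ev$start, c(0, cumsum(ev$duration)[-nrow(ev)]))
    expect_length(tr$samples, 50000)
  }
})

test_that("two-state trace: open fraction near stationary beta/(alpha+beta)", {
  tr <- simulate_two_state_trace(50, 12.5, duration = 200,
                                 sampling_rate = 2000, noise_sd = 0,
                                 filter_cutoff = NULL, seed = 42)
  ev <- tr$true_events
  frac_open <- sum(ev$duration[ev$state == "open"]) / sum(ev$duration)
  # Monte-Carlo s.e. from the event list itself: open fraction is a ratio
  # of sums of exponentials; use the per-cycle spread
  n_cyc <- sum(ev$state == "open")
  se <- sqrt(0.8 * 0.2 / n_cyc) * 2   # conservative
  expect_lt(abs(frac_open - 0.8), 3 * se)
})

test_that("dwell-time means converge to reciprocal rates", {
  # long enough that the 5% bound sits several s.e. out
  tr <- simulate_two_state_trace(50, 12.5, duration = 600,
                                 sampling_rate = 1000, noise_sd = 0,
                                 filter_cutoff = NULL, seed = 9)
  ev <- tr$true_events[-c(1, nrow(tr$true_events)), ]
  expect_gt(nrow(ev), 2000)
  m_closed <- mean(ev$duration[ev$state == "closed"])
  m_open <- mean(ev$duration[ev$state == "open"])
  expect_lt(abs(m_closed - 1 / 50) / (1 / 50), 0.05)
  expect_lt(abs(m_open - 1 / 12.5) / (1 / 12.5), 0.05)
})

test_that("generators are bit-identical under a repeated seed", {
  a <- simulate_two_state_trace(50, 12.5, 5, 5000, seed = 3)
  b <- simulate_two_state_trace(50, 12.5, 5, 5000, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$true_events, b$true_events)

  expect_identical(simulate_macroscopic_patch(100, 0.5, 1, 1000, seed = 4),
                   simulate_macroscopic_patch(100, 0.5, 1, 1000, seed = 4))

  d1 <- simulate_dose_response(975.8, 4.263, 1.74, c(10, 50, 200, 1000),
                               seed = 5)
  d2 <- simulate_dose_response(975.8, 4.263, 1.74, c(10, 50, 200, 1000),
                               seed = 5)
  expect_identical(d1$response, d2$response)

  s1 <- simulate_emission_spectrum(480, 25, 0.3, noise_sd = 1, seed = 6)
  s2 <- simulate_emission_spectrum(480, 25, 0.3, noise_sd = 1, seed = 6)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("macroscopic patch matches binomial moments and degenerate cases", {
  x <- simulate_macroscopic_patch(100, 0.81, 1, 1e5, seed = 11)
  se_mean <- sqrt(100 * 0.81 * 0.19 / 1e5)
  expect_lt(abs(mean(x) - 81), 4 * se_mean)
  expect_lt(abs(var(x) - 15.39) / 15.39, 0.1)

  expect_true(all(simulate_macroscopic_patch(50, 1, 2, 100, seed = 1) == 100))
  expect_true(all(simulate_macroscopic_patch(50, 0, 2, 100, seed = 1) == 0))
  expect_error(simulate_macroscopic_patch(50, 1.2, 1, 10, seed = 1),
               "p_open")
})

test_that("dose-response means follow the gating-scheme Hill law", {
  ec50 <- 975.8 / (1 + 4.263)
  expect_equal(ec50, 185.4, tolerance = 1e-3)
  ds <- simulate_dose_response(975.8, 4.263, 1.74,
                               c(50, ec50, 500, 5e5), noise_sd = 0,
                               n_replicates = 1, seed = 1)
  po_max <- 4.263 / 5.263
  # midpoint and saturation of the Hill law
  expect_equal(ds$response[ds$concentration_uM == ec50], po_max / 2,
               tolerance = 1e-10)
  expect_equal(ds$response[ds$concentration_uM == 5e5], po_max,
               tolerance = 1e-3)
  expect_error(simulate_dose_response(1, 1, 1, numeric(0), seed = 1),
               "non-empty")
})

test_that("mutant series is exactly collinear with slope phi_true", {
  s <- simulate_mutant_series(50, 12.5, 0.7, c(-0.6, -0.3, 0, 0.3))
  slope <- ols_slope(log10(s$k_eq), log10(s$opening_rate))
  expect_equal(slope, 0.7, tolerance = 1e-12)
  # member-wise invariant to machine tolerance
  wt <- s[s$mutant == "WT", ]
  dlogk <- log10(s$k_eq) - log10(wt$k_eq)
  expect_equal(log10(s$opening_rate) - log10(wt$opening_rate),
               0.7 * dlogk, tolerance = 1e-12)

  s1 <- simulate_mutant_series(50, 12.5, 1, c(-1, 0, 1))
  expect_true(all(s1$closing_rate == 12.5))
  s0 <- simulate_mutant_series(50, 12.5, 0, c(-1, 0, 1))
  expect_true(all(s0$opening_rate == 50))
  expect_error(simulate_mutant_series(50, 12.5, 1.2, 0), "phi_true")
})

test_that("emission spectrum peaks at the stated mode", {
  sp <- simulate_emission_spectrum(480, 25, 0, noise_sd = 0, seed = 1)
  expect_equal(sp$wavelength_nm[which.max(sp$intensity)], 480)
  flat <- simulate_emission_spectrum(480, 25, 0.3, amplitude = 0,
                                     baseline = 7, noise_sd = 0, seed = 1)
  expect_true(all(flat$intensity == 7))
  # skewed: dense evaluation of the generating profile has mode at peak
  g <- seq(470, 490, by = 0.01)
  v <- emg_profile(g, 480, 25, 0.3)
  expect_lt(abs(g[which.max(v)] - 480), 0.02)
  expect_error(simulate_emission_spectrum(480, -1, seed = 1), "width")
})

test_that("sub-sample events are kept in truth but may vanish from samples", {
  # dense event structure sampled coarsely: samples see only the state at
  # each instant, the truth keeps every dwell
  tr <- simulate_two_state_trace(2000, 2000, duration = 1,
                                 sampling_rate = 100, noise_sd = 0,
                                 filter_cutoff = NULL, seed = 8)
  expect_gt(nrow(tr$true_events), length(tr$samples))
  expect_length(tr$samples, 100)
})

test_that("file writers and readers round-trip the interchange schemas", {
  td <- withr::local_tempdir()
  tr <- simulate_two_state_trace(50, 12.5, 1, 1000, seed = 2)
  f1 <- write_trace_csv(tr, file.path(td, "t.csv"))
  back <- read_trace_csv(f1)
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  expect_equal(back$sampling_rate, 1000, tolerance = 1e-6)

  f2 <- write_trace_raw(tr, file.path(td, "t.f32"))
  raw <- read_trace_raw(f2)
  expect_equal(raw$samples, tr$samples, tolerance = 1e-6)
  expect_equal(raw$sampling_rate, 1000)

  ds <- simulate_dose_response(975.8, 4.263, 1.74, c(10, 50, 200, 1000),
                               seed = 5)
  f3 <- write_dose_csv(ds, file.path(td, "d.csv"))
  expect_equal(read_dose_csv(f3)$response, ds$response, tolerance = 1e-12)

  sp <- simulate_emission_spectrum(480, 25, 0.3, noise_sd = 0, seed = 1)
  f4 <- write_spectrum_csv(sp, file.path(td, "s.csv"))
  expect_equal(read_spectrum_csv(f4)$intensity, sp$intensity,
               tolerance = 1e-12)

  f5 <- write_events_tsv(tr$true_events, file.path(td, "e.tsv"))
  ev <- read.delim(f5)
  expect_equal(nrow(ev), nrow(tr$true_events))
  expect_equal(ev$duration_s, tr$true_events$duration, tolerance = 1e-12)
})

test_that("generator input validation rejects bad arguments", {
  expect_error(simulate_two_state_trace(-1, 10, 1, 1000, seed = 1), "rate")
  expect_error(simulate_two_state_trace(10, 10, 0, 1000, seed = 1),
               "duration")
  expect_error(simulate_two_state_trace(10, 10, 1, 1000), "seed")
})
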