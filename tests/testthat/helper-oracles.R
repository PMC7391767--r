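# Independent oracles used across tests. These deliberately avoid the
# package's own fitting/estimation code paths.

# Brute-force grid-search Hill fit: minimizes RSS over a dense lattice.
grid_search_hill <- function(conc, resp,
                             ec50_grid = NULL, n_grid = NULL,
                             rmax_grid = NULL) {
  if (is.null(ec50_grid))
    ec50_grid <- 10^seq(log10(min(conc)), log10(max(conc)),
                        length.out = 120)
  if (is.null(n_grid)) n_grid <- seq(0.5, 3, by = 0.02)
  if (is.null(rmax_grid))
    rmax_grid <- seq(0.5 * max(resp), 1.2 * max(resp), length.out = 80)
  best <- list(rss = Inf)
  for (e in ec50_grid) {
    frac <- outer(conc, n_grid, function(cc, nn)
      cc^nn / (cc^nn + e^nn))
    for (j in seq_along(n_grid)) for (r in rmax_grid) {
      rss <- sum((resp - r * frac[, j])^2)
      if (rss < best$rss)
        best <- list(ec50 = e, n = n_grid[j], rmax = r, rss = rss)
    }
  }
  best
}

# Closed-form OLS slope for (x, y) pairs.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Render a ground-truth event list to noise-free samples (point sampling),
# independent of the package's renderers.
render_truth <- function(events, sampling_rate, duration, open_current = 1) {
  n <- round(duration * sampling_rate)
  t_samp <- (seq_len(n) - 1) / sampling_rate
  ends <- cumsum(events$duration)
  idx <- findInterval(t_samp, c(0, ends))
  idx[idx < 1] <- 1; idx[idx > nrow(events)] <- nrow(events)
  ifelse(events$state[idx] == "open", open_current, 0)
}

# Draw an exponential-dwell event list directly (independent generator for
# idealization oracles). All dwells are resampled until >= min_dwell.
draw_event_list <- function(opening_rate, closing_rate, n_events,
                            min_dwell = 0) {
  states <- rep(c("closed", "open"), length.out = n_events)
  durs <- numeric(n_events)
  for (i in seq_len(n_events)) {
    rate <- if (states[i] == "closed") opening_rate else closing_rate
    repeat {
      d <- rexp(1, rate)
      if (d >= min_dwell) break
    }
    durs[i] <- d
  }
  data.frame(state = states,
             start = c(0, cumsum(durs)[-n_events]),
             duration = durs, stringsAsFactors = FALSE)
}
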