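#' Locate baseline and open current levels from an all-point histogram
#'
#' Builds an all-point amplitude histogram of the trace, picks the two
#' dominant, well-separated modes, and refines each by a local Gaussian
#' (quadratic-in-log) fit around the peak. The lower mode is the baseline,
#' the upper the open level; the unitary current is their difference and the
#' chord conductance i/V follows from the holding voltage.
#'
#' @param samples Current samples, pA (a numeric vector or a
#'   `simulated_trace`).
#' @param voltage Holding voltage in mV (for the conductance); optional.
#' @param n_bins Histogram bins (default 256).
#' @param min_separation Minimum mode separation as a fraction of the data
#'   range (default 0.25).
#' @return An `amplitude_fit` list: `baseline_mean`, `open_mean`,
#'   `unitary_current` (pA), `conductance_pS` (NA when `voltage` missing or
#'   the histogram is unimodal), `n_levels`, and histogram diagnostics
#'   (`breaks`, `counts`).
#' @export
detect_levels <- function(samples, voltage = NULL, n_bins = 256,
                          min_separation = 0.25) {
  if (inherits(samples, "simulated_trace")) samples <- samples$samples
  if (length(samples) == 0) stop("trace is empty", call. = FALSE)
  rng <- range(samples)
  if (diff(rng) == 0) {
    return(structure(list(baseline_mean = rng[1], open_mean = NA_real_,
                          unitary_current = NA_real_,
                          conductance_pS = NA_real_, n_levels = 1L,
                          breaks = NULL, counts = NULL),
                     class = "amplitude_fit"))
  }
  h <- graphics::hist(samples, breaks = n_bins, plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  # local maxima of the (lightly smoothed) histogram
  sm <- stats::filter(cnt, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  sm <- as.numeric(sm)
  is_pk <- which(diff(sign(diff(c(-Inf, sm, -Inf)))) < 0)
  pk <- is_pk[order(sm[is_pk], decreasing = TRUE)]
  sep_min <- min_separation * diff(rng)
  lead <- pk[1]
  # a genuine second level must be separated and, once samples are split
  # at the midpoint of the two candidate modes, the groups must be far
  # apart relative to their own spreads -- the shoulder bumps of a
  # unimodal (all-closed) histogram fail this
  cand <- pk[abs(mids[pk] - mids[lead]) >= sep_min &
               sm[pk] >= 0.02 * sm[lead]]
  second <- NA_integer_
  for (cd in cand) {
    thr <- (mids[lead] + mids[cd]) / 2
    lo <- samples[samples <= thr]; hi <- samples[samples > thr]
    if (length(lo) < 10 || length(hi) < 10) next
    gap <- abs(mean(hi) - mean(lo))
    spread <- stats::sd(lo) + stats::sd(hi)
    if (!is.finite(spread) || spread == 0 || gap > 3 * spread) {
      second <- cd
      break
    }
  }
  refine <- function(ipk) {
    # Gaussian refinement: parabola through log-counts at the peak triplet
    i0 <- max(2, min(length(mids) - 1, ipk))
    y <- log(pmax(cnt[(i0 - 1):(i0 + 1)], 0.5))
    denom <- y[1] - 2 * y[2] + y[3]
    if (!is.finite(denom) || denom >= 0) return(mids[i0])
    mids[i0] + 0.5 * (y[1] - y[3]) / denom * (mids[2] - mids[1])
  }
  if (is.na(second)) {
    return(structure(list(baseline_mean = refine(lead), open_mean = NA_real_,
                          unitary_current = NA_real_,
                          conductance_pS = NA_real_, n_levels = 1L,
                          breaks = h$breaks, counts = cnt),
                     class = "amplitude_fit"))
  }
  levels <- sort(c(refine(lead), refine(second)))
  i_unit <- levels[2] - levels[1]
  g <- if (is.null(voltage)) NA_real_ else i_unit / voltage * 1000  # pA/mV -> pS
  structure(list(baseline_mean = levels[1], open_mean = levels[2],
                 unitary_current = i_unit, conductance_pS = g,
                 n_levels = 2L, breaks = h$breaks, counts = cnt),
            class = "amplitude_fit")
}

#' Idealize a single-channel trace by the half-amplitude method
#'
#' Threshold-crossing idealization: each sample is assigned closed or open
#' by which side of the midpoint between the baseline and open levels it
#' falls on (samples exactly at threshold keep the previous sample's state);
#' runs of equal state become dwell events. Events shorter than the dead
#' time are then removed retrospectively by merging each into the preceding
#' event and coalescing the resulting same-state neighbours, iterating until
#' no interior event is shorter than the dead time. The first and last
#' events are duration-censored by the record boundaries and are never
#' merged away; they are flagged as edge events.
#'
#' @param trace A `simulated_trace`, a list with `samples` and
#'   `sampling_rate`, or a numeric vector (then `sampling_rate` is needed).
#' @param baseline,open_level Closed and open current levels, pA.
#' @param dead_time Shortest resolvable event, seconds (0.32 ms in typical
#'   use). Values below one sample period trigger a warning and no merging.
#' @param sampling_rate Hz; taken from `trace` when present.
#' @return An `idealized_record` list: `events` (data.frame `state`,
#'   `start`, `duration`, `edge`), `dead_time`, `total_duration`,
#'   `threshold_current`, `sampling_rate`.
#' @export
idealize_half_amplitude <- function(trace, baseline, open_level,
                                    dead_time = 0.32e-3,
                                    sampling_rate = NULL) {
  if (is.list(trace)) {
    if (is.null(sampling_rate)) sampling_rate <- trace$sampling_rate
    samples <- trace$samples
  } else samples <- trace
  if (is.null(sampling_rate))
    stop("sampling_rate is required for a bare sample vector", call. = FALSE)
  if (open_level == baseline)
    stop("open_level must differ from baseline", call. = FALSE)
  if (dead_time < 0) stop("dead_time must be >= 0", call. = FALSE)
  dt <- 1 / sampling_rate
  if (dead_time > 0 && dead_time < dt) {
    warning("dead_time shorter than one sample period; no events merged")
    dead_time <- 0
  }
  thr <- (baseline + open_level) / 2
  flip <- open_level < baseline          # allow inward (negative) openings
  x <- if (flip) -samples else samples
  th <- if (flip) -thr else thr
  state <- x > th
  ties <- x == th
  if (any(ties)) {
    # a tied sample keeps the previous state; leading ties are closed
    for (i in which(ties)) state[i] <- if (i == 1) FALSE else state[i - 1]
  }
  r <- rle(state)
  durs <- r$lengths * dt
  states <- ifelse(r$values, "open", "closed")
  merged <- impose_dead_time(states, durs, dead_time)
  n_ev <- length(merged$durations)
  events <- data.frame(
    state = merged$states,
    start = c(0, cumsum(merged$durations)[-n_ev]),
    duration = merged$durations,
    edge = seq_len(n_ev) %in% c(1L, n_ev),
    stringsAsFactors = FALSE)
  structure(list(events = events, dead_time = dead_time,
                 total_duration = length(samples) * dt,
                 threshold_current = thr, sampling_rate = sampling_rate),
            class = "idealized_record")
}

# Retrospective dead-time imposition: repeatedly absorb interior events
# shorter than dead_time into their predecessor, then coalesce adjacent
# same-state events, until stable. One stack pass per iteration.
impose_dead_time <- function(states, durations, dead_time) {
  if (dead_time <= 0 || length(durations) <= 1)
    return(coalesce_events(states, durations))
  repeat {
    st <- character(0); du <- numeric(0)
    for (i in seq_along(durations)) {
      s <- states[i]; d <- durations[i]
      if (length(st) > 0 && d < dead_time && i < length(durations)) {
        du[length(du)] <- du[length(du)] + d   # absorb into predecessor
      } else if (length(st) > 0 && s == st[length(st)]) {
        du[length(du)] <- du[length(du)] + d   # coalesce same state
      } else {
        st <- c(st, s); du <- c(du, d)
      }
    }
    # after absorption the successor may share the predecessor's state
    cz <- coalesce_events(st, du)
    st <- cz$states; du <- cz$durations
    interior <- setdiff(seq_along(du), c(1L, length(du)))
    if (!length(interior) || all(du[interior] >= dead_time)) break
    states <- st; durations <- du
  }
  list(states = st, durations = du)
}

coalesce_events <- function(states, durations) {
  if (length(states) <= 1) return(list(states = states, durations = durations))
  grp <- cumsum(c(TRUE, states[-1] != states[-length(states)]))
  list(states = tapply(states, grp, `[`, 1L, simplify = TRUE) |> as.character(),
       durations = as.numeric(tapply(durations, grp, sum)))
}

#' Estimate two-state rates from an idealized record
#'
#' Dwell times of a two-state channel are exponential, so the maximum-
#' likelihood rate is the reciprocal mean dwell: opening rate = 1 / mean
#' closed dwell, closing rate = 1 / mean open dwell, each with standard
#' error rate/sqrt(n). Edge events (first/last, censored by the record
#' boundary) are excluded. The equilibrium constant is the ratio of
#' forward to backward rate. An optional first-order missed-event
#' correction subtracts the dead time from every dwell before averaging
#' (off by default).
#'
#' @param record An `idealized_record`.
#' @param dead_time_correction Subtract the record's dead time from each
#'   dwell before averaging (default `FALSE`).
#' @return A `kinetic_rates` list: `opening_rate`, `closing_rate`, `k_eq`,
#'   `se_opening`, `se_closing`, `n_closed_events`, `n_open_events`.
#' @export
estimate_rates <- function(record, dead_time_correction = FALSE) {
  ev <- record$events
  interior <- ev[!ev$edge, , drop = FALSE]
  cl <- interior$duration[interior$state == "closed"]
  op <- interior$duration[interior$state == "open"]
  if (length(cl) < 2 || length(op) < 2)
    stop("need >= 2 interior events of each state to estimate rates",
         call. = FALSE)
  if (dead_time_correction) {
    cl <- pmax(cl - record$dead_time, .Machine$double.eps)
    op <- pmax(op - record$dead_time, .Machine$double.eps)
  }
  beta <- 1 / mean(cl)     # closed -> open (forward)
  alpha <- 1 / mean(op)    # open -> closed (backward)
  structure(list(opening_rate = beta, closing_rate = alpha,
                 k_eq = beta / alpha,
                 se_opening = beta / sqrt(length(cl)),
                 se_closing = alpha / sqrt(length(op)),
                 n_closed_events = length(cl),
                 n_open_events = length(op)),
            class = "kinetic_rates")
}

#' Open probability from an idealized record
#'
#' Po = total open time / record duration.
#'
#' @param record An `idealized_record` (or any list with an `events`
#'   data.frame and `total_duration`).
#' @return Open probability in \[0, 1\].
#' @export
open_probability <- function(record) {
  if (record$total_duration <= 0)
    stop("total_duration must be positive", call. = FALSE)
  sum(record$events$duration[record$events$state == "open"]) /
    record$total_duration
}

#' Bronsted (rate-equilibrium) fit of a mutant series: the Phi value
#'
#' Ordinary least-squares fit of log10(opening rate) against
#' log10(equilibrium constant) across mutants at one site. The slope is the
#' Phi value: Phi near 1 means mutations act almost entirely through the
#' opening rate (the perturbed residue moves early in the activation
#' pathway, in the single-pathway reading); Phi near 0 means they act
#' through the closing rate (late movement).
#'
#' @param points Data.frame with columns `k_eq` and `opening_rate` (one row
#'   per mutant; a `mutant_series` works directly).
#' @param min_points Minimum mutants required (default 3).
#' @return A `phi_result` list: `phi`, `intercept`, `se_phi`, `r_squared`,
#'   `n`, `points`.
#' @export
fit_bronsted <- function(points, min_points = 3) {
  if (nrow(points) < min_points)
    stop("need >= ", min_points, " mutants for a Bronsted fit", call. = FALSE)
  lk <- log10(points$k_eq)
  lb <- log10(points$opening_rate)
  if (length(unique(lk)) < 2)
    stop("degenerate series: equilibrium constants are not distinct",
         call. = FALSE)
  fit <- stats::lm(lb ~ lk)
  sm <- suppressWarnings(summary(fit))  # exact series fit perfectly
  r2 <- sm$r.squared
  # constant opening rates (Phi = 0) fit exactly but leave r^2 undefined
  if (is.nan(r2) && sum(stats::residuals(fit)^2) < 1e-20) r2 <- 1
  structure(list(phi = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_phi = sm$coefficients[2, "Std. Error"],
                 r_squared = r2,
                 n = nrow(points), points = points),
            class = "phi_result")
}

#' Render an idealized record back to a piecewise-constant current
#'
#' Utility for idempotence checks and plotting: closed events at
#' `baseline`, open events at `open_level`, point-sampled at the record's
#' sampling rate.
#'
#' @param record An `idealized_record`.
#' @param baseline,open_level Levels in pA.
#' @return Numeric sample vector.
#' @export
render_events <- function(record, baseline = 0, open_level = 1) {
  ev <- record$events
  n <- round(record$total_duration * record$sampling_rate)
  # integer requantization: durations that are whole numbers of samples
  # map back to exactly those sample counts (idempotence-safe)
  ends <- pmin(round(cumsum(ev$duration) * record$sampling_rate), n)
  counts <- diff(c(0, ends))
  counts[length(counts)] <- counts[length(counts)] + (n - sum(counts))
  rep(ifelse(ev$state == "open", open_level, baseline), counts)
}
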