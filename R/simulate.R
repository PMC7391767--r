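#' Simulate a two-state single-channel current trace
#'
#' Draws a continuous-time trajectory of the simple closed <-> open gating
#' scheme (exponential dwell times at the stated rates, Gillespie sequence),
#' renders it to a uniformly sampled current, adds Gaussian recording noise,
#' and optionally applies a low-pass filter emulating the recording chain
#' (10 kHz sampling, 2.9 kHz Bessel-like filtering are typical patch-clamp
#' settings). The ground-truth event list is returned alongside the samples
#' so idealization and rate estimation can be checked against it.
#'
#' The chain starts in the closed state by default (a resting channel before
#' agonist); pass `initial_state = "open"` to override. Samples are rendered
#' by point sampling: each sample takes the state occupied at that instant,
#' so events shorter than one sample period may leave no sample behind but
#' are still present in `true_events`.
#'
#' @param opening_rate Closed-to-open rate constant (per second), >= 0.
#' @param closing_rate Open-to-closed rate constant (per second), >= 0.
#' @param duration Trace length in seconds, > 0.
#' @param sampling_rate Samples per second (Hz), > 0.
#' @param open_current Open-level current in pA (closed level is 0 pA).
#' @param noise_sd Standard deviation of additive Gaussian noise, pA.
#' @param filter_cutoff -3 dB cutoff of the Gaussian low-pass filter in Hz,
#'   or `NULL` for no filtering.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @param initial_state `"closed"` (default) or `"open"`.
#' @return An object of class `simulated_trace`: list with `samples` (pA),
#'   `time` (s), `sampling_rate`, `true_events` (data.frame `state`, `start`,
#'   `duration`), and `params`.
#' @export
simulate_two_state_trace <- function(opening_rate, closing_rate, duration,
                                     sampling_rate = 10000,
                                     open_current = 1, noise_sd = 0.15,
                                     filter_cutoff = 2900, seed,
                                     initial_state = c("closed", "open")) {
  initial_state <- match.arg(initial_state)
  if (opening_rate < 0 || closing_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    events <- gillespie_two_state(opening_rate, closing_rate, duration,
                                  initial_state)
    n <- round(duration * sampling_rate)
    t_samp <- (seq_len(n) - 1L) / sampling_rate
    # state at each sample instant: index of the dwell containing it
    # a sample exactly at a transition instant takes the new state
    bounds <- cumsum(events$duration)
    idx <- findInterval(t_samp, c(0, bounds))
    idx[idx < 1L] <- 1L
    idx[idx > nrow(events)] <- nrow(events)
    clean <- ifelse(events$state[idx] == "open", open_current, 0)
    samples <- clean
    if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
    if (!is.null(filter_cutoff) && is.finite(filter_cutoff))
      samples <- gaussian_lowpass(samples, filter_cutoff, sampling_rate)
    structure(list(
      samples = samples, time = t_samp, sampling_rate = sampling_rate,
      true_events = events,
      params = list(opening_rate = opening_rate, closing_rate = closing_rate,
                    duration = duration, open_current = open_current,
                    baseline_current = 0, noise_sd = noise_sd,
                    filter_cutoff = filter_cutoff, seed = as.integer(seed))),
      class = "simulated_trace")
  })
}

# Gillespie dwell sequence for closed <-> open. Because the state strictly
# alternates, dwells are drawn in interleaved vectorized blocks; the last
# dwell is truncated at `duration` so durations sum exactly.
gillespie_two_state <- function(opening_rate, closing_rate, duration,
                                initial_state) {
  first_rate <- if (initial_state == "closed") opening_rate else closing_rate
  secnd_rate <- if (initial_state == "closed") closing_rate else opening_rate
  if (first_rate == 0)                       # absorbing initial state
    return(data.frame(state = initial_state, start = 0, duration = duration,
                      stringsAsFactors = FALSE))
  other <- if (initial_state == "closed") "open" else "closed"
  mean_cycle <- 1 / first_rate + if (secnd_rate > 0) 1 / secnd_rate else Inf
  durs <- numeric(0)
  repeat {
    n_cyc <- if (is.finite(mean_cycle))
      max(16L, ceiling(duration / mean_cycle * 1.25) + 16L) else 1L
    d1 <- stats::rexp(n_cyc, first_rate)
    if (secnd_rate == 0) {                   # absorbing second state
      durs <- c(d1[1], duration)             # truncated below
    } else {
      d2 <- stats::rexp(n_cyc, secnd_rate)
      blk <- as.vector(rbind(d1, d2))        # interleave
      durs <- c(durs, blk)
    }
    if (sum(durs) >= duration) break
  }
  ends <- cumsum(durs)
  n_ev <- which(ends >= duration)[1]
  durs <- durs[seq_len(n_ev)]
  durs[n_ev] <- duration - if (n_ev > 1) ends[n_ev - 1] else 0
  states <- rep(c(initial_state, other), length.out = n_ev)
  data.frame(state = states,
             start = c(0, cumsum(durs)[-n_ev]),
             duration = durs, stringsAsFactors = FALSE)
}

# Gaussian low-pass whose -3 dB point is `cutoff`. For a Gaussian impulse
# response with time s.d. sigma, |H(f)| = exp(-2 pi^2 sigma^2 f^2); setting
# |H(fc)|^2 = 1/2 gives sigma = sqrt(ln 2)/(2 pi fc).
gaussian_lowpass <- function(x, cutoff, sampling_rate) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff) * sampling_rate  # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  # edge-replicate padding keeps the trace length and avoids edge droop;
  # direct convolution: the kernel is a handful of taps, so this is O(n k)
  # with no FFT length pathologies
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Simulate a stationary macroscopic patch current
#'
#' Each sample is an independent binomial draw of open channels times the
#' unitary current: the idealized steady-state multichannel patch underlying
#' stationary noise analysis (mean N i Po, variance N i^2 Po(1-Po)).
#'
#' @param n_channels Number of channels in the patch, >= 1.
#' @param p_open Per-channel open probability in \[0, 1\].
#' @param unitary_current Single-channel current i in pA.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed.
#' @return Numeric vector of currents (pA).
#' @export
simulate_macroscopic_patch <- function(n_channels, p_open, unitary_current,
                                       n_samples, seed) {
  if (p_open < 0 || p_open > 1) stop("p_open must be in [0, 1]", call. = FALSE)
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::with_seed(as.integer(seed),
    stats::rbinom(n_samples, size = n_channels, prob = p_open) * unitary_current)
}

#' Simulate a Hill-shaped dose-response dataset
#'
#' Mean response at concentration c follows the ligand-gating prediction
#' Po_max c^nH / (c^nH + EC50^nH) with EC50 = Kd/(1+L) and Po_max = L/(1+L);
#' replicates add Gaussian noise truncated at zero. Generating parameters are
#' kept in `$truth` so fits can be scored against them.
#'
#' @param k_d Ligand dissociation constant, micromolar.
#' @param l_eq Gating equilibrium constant L (dimensionless).
#' @param hill_n Hill coefficient.
#' @param concentrations Micromolar concentrations (strictly positive).
#' @param noise_sd Replicate noise s.d. on the normalized-response scale.
#' @param n_replicates Replicates per concentration, >= 1.
#' @param seed Integer seed.
#' @param ligand,genotype Labels carried through to outputs.
#' @return A `dose_response_dataset`: tibble (`ligand`, `genotype`,
#'   `concentration_uM`, `replicate`, `response`) with attribute `truth`.
#' @export
simulate_dose_response <- function(k_d, l_eq, hill_n, concentrations,
                                   noise_sd = 0.02, n_replicates = 5, seed,
                                   ligand = "menthol", genotype = "WT") {
  if (k_d <= 0 || l_eq <= 0 || hill_n <= 0)
    stop("k_d, l_eq and hill_n must be positive", call. = FALSE)
  if (length(concentrations) == 0)
    stop("concentrations must be non-empty", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  concentrations <- sort(concentrations)
  ec50 <- k_d / (1 + l_eq)
  po_max <- l_eq / (1 + l_eq)
  mu <- po_max * concentrations^hill_n / (concentrations^hill_n + ec50^hill_n)
  withr::with_seed(as.integer(seed), {
    resp <- rep(mu, each = n_replicates)
    if (noise_sd > 0)
      resp <- pmax(0, resp + stats::rnorm(length(resp), 0, noise_sd))
    out <- tibble::tibble(
      ligand = ligand, genotype = genotype,
      concentration_uM = rep(concentrations, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(concentrations)),
      response = resp)
    attr(out, "truth") <- list(k_d = k_d, l_eq = l_eq, hill_n = hill_n,
                               ec50 = ec50, po_max = po_max,
                               noise_sd = noise_sd, seed = as.integer(seed))
    class(out) <- c("dose_response_dataset", class(out))
    out
  })
}

#' Construct a mutant rate series with an exact Phi value
#'
#' Builds per-mutant opening/closing rates around a wild-type pair so that
#' log10(opening rate) is exactly collinear with log10(equilibrium constant)
#' with slope `phi_true`: log10 beta = log10 beta_wt + Phi dlogK and
#' log10 alpha = log10 alpha_wt - (1 - Phi) dlogK. A Bronsted fit on these
#' rates must recover `phi_true` to machine precision.
#'
#' @param wt_opening,wt_closing Wild-type opening/closing rates (per second).
#' @param phi_true Target Phi in \[0, 1\].
#' @param delta_log10_k Per-mutant shifts of log10 K (0 = wild type).
#' @param site Site label.
#' @param seed Integer seed, recorded for provenance (construction is
#'   deterministic).
#' @return A `mutant_series`: tibble (`site`, `mutant`, `opening_rate`,
#'   `closing_rate`, `k_eq`) with attribute `phi_true`.
#' @export
simulate_mutant_series <- function(wt_opening, wt_closing, phi_true,
                                   delta_log10_k, site = "site", seed = 1L) {
  if (wt_opening <= 0 || wt_closing <= 0)
    stop("wild-type rates must be positive", call. = FALSE)
  if (phi_true < 0 || phi_true > 1)
    stop("phi_true must be in [0, 1]", call. = FALSE)
  beta <- wt_opening * 10^(phi_true * delta_log10_k)
  alpha <- wt_closing * 10^(-(1 - phi_true) * delta_log10_k)
  out <- tibble::tibble(
    site = site,
    mutant = ifelse(delta_log10_k == 0, "WT",
                    sprintf("mut%+0.2f", delta_log10_k)),
    opening_rate = beta, closing_rate = alpha, k_eq = beta / alpha)
  attr(out, "phi_true") <- phi_true
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("mutant_series", class(out))
  out
}

#' Simulate a skewed fluorescence emission spectrum
#'
#' Intensity = baseline + amplitude * s(lambda) + noise, where s is an
#' exponentially modified Gaussian reparameterized so its mode sits exactly
#' at `peak` and its height there is 1 (see [emg_profile()]); `skew = 0`
#' reduces to a symmetric Gaussian. Emulates ANAP emission spectra whose
#' peak position reports the local environment polarity.
#'
#' @param peak Mode wavelength, nm.
#' @param width Gaussian width sigma, nm, > 0.
#' @param skew Exponential tail scale as a multiple of `width`; sign sets the
#'   tail direction (positive = red tail), 0 = symmetric.
#' @param amplitude Peak height above baseline, arbitrary units.
#' @param baseline Constant offset, arbitrary units.
#' @param noise_sd Gaussian noise s.d., arbitrary units.
#' @param grid Wavelength grid (nm), strictly increasing.
#' @param seed Integer seed.
#' @return A `synthetic_spectrum`: tibble (`wavelength_nm`, `intensity`)
#'   with attribute `truth`.
#' @export
simulate_emission_spectrum <- function(peak, width, skew = 0, amplitude = 1,
                                       baseline = 0, noise_sd = 0,
                                       grid = seq(400, 620, by = 1), seed) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    s <- emg_profile(grid, peak, width, skew)
    intens <- baseline + amplitude * s
    if (noise_sd > 0) intens <- intens + stats::rnorm(length(grid), 0, noise_sd)
    out <- tibble::tibble(wavelength_nm = grid, intensity = intens)
    attr(out, "truth") <- list(peak = peak, width = width, skew = skew,
                               amplitude = amplitude, baseline = baseline,
                               noise_sd = noise_sd, seed = as.integer(seed))
    class(out) <- c("synthetic_spectrum", class(out))
    out
  })
}

# ---- plain-text writers -------------------------------------------------

#' Write synthetic objects to the interchange CSV/TSV schemas
#'
#' `write_trace_csv` writes `time_s,current_pA`; `write_dose_csv` writes
#' `ligand,genotype,concentration_uM,replicate,response`;
#' `write_spectrum_csv` writes `wavelength_nm,intensity`; `write_events_tsv`
#' writes `state,start_s,duration_s`.
#'
#' @param trace,data,spectrum,events Objects from the simulators (events may
#'   be any data.frame with `state`, `start`, `duration`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time,
                              current_pA = trace$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_dose_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, c("ligand", "genotype",
                                           "concentration_uM", "replicate",
                                           "response")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum)[, c("wavelength_nm", "intensity")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(data.frame(state = events$state,
                                start_s = events$start,
                                duration_s = events$duration),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#' @param path CSV path with columns `time_s`, `current_pA`.
#' @return List with `samples`, `time`, `sampling_rate`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "current_pA") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  list(samples = d$current_pA, time = d$time_s, sampling_rate = fs)
}
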