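#' Mean and variance of a stationary current segment
#'
#' @param samples Current samples, pA (>= 2 of them).
#' @return A `segment_stats` list: `mean_current` (I), `variance`
#'   (unbiased sample variance, sigma^2), `n_samples`.
#' @export
segment_stats <- function(samples) {
  if (length(samples) < 2)
    stop("need >= 2 samples for segment statistics", call. = FALSE)
  structure(list(mean_current = mean(samples),
                 variance = stats::var(samples),
                 n_samples = length(samples)),
            class = "segment_stats")
}

#' Channel count from stationary noise: N = I^2 / (i I - sigma^2)
#'
#' For N identical, independent channels with unitary current i and open
#' probability Po, the steady-state current has mean I = N i Po and variance
#' sigma^2 = N i^2 Po (1 - Po); eliminating Po gives
#' N = I^2 / (i I - sigma^2). N is reported as a real number — rounding to
#' an integer belongs in reports, not in the estimate.
#'
#' @param i_mean Mean current I, pA, > 0.
#' @param variance Current variance sigma^2, pA^2.
#' @param unitary_current Single-channel current i, pA, > 0 (measured
#'   experimentally, e.g. via [detect_levels()]).
#' @param background_variance Optional instrumentation variance to subtract
#'   from `variance` before applying the identity.
#' @return Estimated channel count (real).
#' @export
channel_count <- function(i_mean, variance, unitary_current,
                          background_variance = 0) {
  if (unitary_current <= 0)
    stop("unitary_current must be positive", call. = FALSE)
  if (i_mean <= 0) stop("mean current must be positive", call. = FALSE)
  v <- variance - background_variance
  denom <- unitary_current * i_mean - v
  if (denom <= 0)
    stop("variance exceeds binomial bound (i*I <= sigma^2): ",
         "channel count undefined", call. = FALSE)
  i_mean^2 / denom
}

#' Open probability from the noise-analysis maximum current
#'
#' The maximum current with every channel open is i_max = N i; the open
#' probability is the ratio of the measured current to that maximum,
#' Po = I / (N i). A ratio slightly above 1 (numerical slack) is clipped;
#' beyond the tolerance it signals an inconsistent N or i.
#'
#' @param measured_current Macroscopic current I, pA.
#' @param n_channels Channel count N, > 0.
#' @param unitary_current Unitary current i, pA, > 0.
#' @param tolerance Allowed overshoot above 1 before erroring (default 0.02).
#' @return Open probability in \[0, 1\].
#' @export
po_from_noise <- function(measured_current, n_channels, unitary_current,
                          tolerance = 0.02) {
  if (n_channels <= 0 || unitary_current <= 0)
    stop("n_channels and unitary_current must be positive", call. = FALSE)
  po <- measured_current / (n_channels * unitary_current)
  if (po > 1 + tolerance)
    stop("Po = ", signif(po, 4), " exceeds 1: measured current is ",
         "inconsistent with the noise-analysis maximum", call. = FALSE)
  min(po, 1)
}

#' Full stationary noise analysis of a current segment
#'
#' Convenience wrapper: segment statistics, channel count, maximum current
#' and open probability in one call.
#'
#' @param samples Current samples, pA.
#' @param unitary_current Unitary current i, pA.
#' @param background_variance Optional variance to subtract.
#' @return A `noise_estimate` list: `n_channels`, `unitary_current`,
#'   `i_max`, `p_open`, `mean_current`, `variance`, `n_samples`.
#' @export
noise_analysis <- function(samples, unitary_current,
                           background_variance = 0) {
  st <- segment_stats(samples)
  n_hat <- channel_count(st$mean_current, st$variance, unitary_current,
                         background_variance)
  structure(list(n_channels = n_hat, unitary_current = unitary_current,
                 i_max = n_hat * unitary_current,
                 p_open = po_from_noise(st$mean_current, n_hat,
                                        unitary_current),
                 mean_current = st$mean_current, variance = st$variance,
                 n_samples = st$n_samples),
            class = "noise_estimate")
}
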