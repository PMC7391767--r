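#' Fit a Hill equation to concentration-response data
#'
#' Least-squares fit of response = Rmax c^n / (c^n + EC50^n) over all
#' replicate points, with multi-start initialization (EC50 started at the
#' geometric mean of the concentrations and at the concentration nearest
#' half-max; n started at 1 and 2) to avoid local minima on steep curves.
#' Among converged starts the fit with the lowest residual sum of squares
#' wins, ties broken toward the smaller EC50.
#'
#' When the responses are Po-calibrated (currents normalized by the
#' noise-analysis maximum), the fitted `response_max` is the maximum open
#' probability Po_max and can be handed to [decompose_gating()].
#'
#' @param data A data.frame with columns `concentration_uM` and `response`
#'   (e.g. from [simulate_dose_response()] or [read_dose_csv()]).
#' @param max_fixed Optional fixed value for the maximum response; when
#'   given only EC50 and n are fitted.
#' @return A `hill_fit` list: `ec50`, `hill_n`, `response_max`, their
#'   standard errors (`se_*`), `rss`, `n_points`, `converged`.
#' @export
fit_hill <- function(data, max_fixed = NULL) {
  conc <- data$concentration_uM
  resp <- data$response
  if (length(unique(conc)) < 4)
    stop("need >= 4 distinct concentrations to fit", call. = FALSE)
  if (any(!is.finite(resp)) || any(resp < 0))
    stop("responses must be finite and >= 0", call. = FALSE)
  if (all(resp == 0))
    stop("no activation: all responses are zero", call. = FALSE)

  rmax0 <- max(resp)
  # concentration whose mean response is nearest half-max
  mu <- tapply(resp, conc, mean)
  cu <- as.numeric(names(mu))
  c_half <- cu[which.min(abs(mu - rmax0 / 2))]
  ec50_starts <- unique(c(exp(mean(log(conc))), c_half))
  n_starts <- c(1, 2)

  best <- NULL
  for (e0 in ec50_starts) for (n0 in n_starts) {
    fit <- if (is.null(max_fixed)) {
      try(minpack.lm::nlsLM(
        resp ~ rmax * conc^n / (conc^n + ec50^n),
        start = list(rmax = rmax0, ec50 = e0, n = n0),
        lower = c(rmax = 1e-8, ec50 = 1e-8, n = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        resp ~ max_fixed * conc^n / (conc^n + ec50^n),
        start = list(ec50 = e0, n = n0),
        lower = c(ec50 = 1e-8, n = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 &&
         stats::coef(fit)[["ec50"]] < best$ec50)) {
      co <- stats::coef(fit)
      se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(co)))
      best <- list(
        ec50 = unname(co[["ec50"]]), hill_n = unname(co[["n"]]),
        response_max = if (is.null(max_fixed)) unname(co[["rmax"]])
                       else max_fixed,
        se_ec50 = unname(se[["ec50"]]), se_hill_n = unname(se[["n"]]),
        se_response_max = if (is.null(max_fixed)) unname(se[["rmax"]])
                          else NA_real_,
        rss = rss, n_points = length(resp), converged = TRUE)
    }
  }
  if (is.null(best)) {
    # honest failure: no start converged (e.g. flat responses)
    return(structure(list(ec50 = NA_real_, hill_n = NA_real_,
                          response_max = NA_real_, se_ec50 = NA_real_,
                          se_hill_n = NA_real_, se_response_max = NA_real_,
                          rss = NA_real_, n_points = length(resp),
                          converged = FALSE), class = "hill_fit"))
  }
  structure(best, class = "hill_fit")
}

#' Decompose an EC50 / Po_max pair into binding and gating constants
#'
#' Under the linear gating scheme C0 <-> C1 <-> O (ligand binding with
#' dissociation constant Kd, then a closed-to-open transition with
#' equilibrium constant L), the apparent dose-response parameters are
#' EC50 = Kd / (1 + L) and Po_max = L / (1 + L). For a partial agonist
#' (Po_max < 1) this inverts uniquely:
#' L = Po_max / (1 - Po_max), Kd = EC50 (1 + L).
#'
#' @param ec50 Half-activating concentration, micromolar, > 0.
#' @param po_max Maximum open probability, strictly in (0, 1).
#' @param se_ec50,se_po_max Optional standard errors, propagated to Kd and L
#'   by the delta method.
#' @return A `gating_decomposition` list: `k_d`, `l_eq`, `se_k_d`, `se_l_eq`,
#'   `ec50`, `po_max`.
#' @export
decompose_gating <- function(ec50, po_max, se_ec50 = NA_real_,
                             se_po_max = NA_real_) {
  if (ec50 <= 0) stop("ec50 must be positive", call. = FALSE)
  if (po_max <= 0) stop("po_max must be positive", call. = FALSE)
  if (po_max >= 1)
    stop("po_max must be < 1: the decomposition requires a partial agonist ",
         "(maximum open probability below unity)", call. = FALSE)
  l_eq <- po_max / (1 - po_max)
  k_d <- ec50 * (1 + l_eq)
  # delta method: dL/dp = 1/(1-p)^2; Kd = e/(1-p) so
  # dKd/de = 1/(1-p), dKd/dp = e/(1-p)^2
  se_l <- if (is.na(se_po_max)) NA_real_ else se_po_max / (1 - po_max)^2
  se_k <- if (is.na(se_ec50) && is.na(se_po_max)) NA_real_ else {
    v <- 0
    if (!is.na(se_ec50)) v <- v + (se_ec50 / (1 - po_max))^2
    if (!is.na(se_po_max)) v <- v + (ec50 * se_po_max / (1 - po_max)^2)^2
    sqrt(v)
  }
  structure(list(k_d = k_d, l_eq = l_eq, se_k_d = se_k, se_l_eq = se_l,
                 ec50 = ec50, po_max = po_max),
            class = "gating_decomposition")
}

#' Recompose apparent dose-response parameters from Kd and L
#'
#' Inverse of [decompose_gating()]: EC50 = Kd/(1+L), Po_max = L/(1+L).
#'
#' @param k_d Dissociation constant, micromolar, > 0.
#' @param l_eq Gating equilibrium constant, > 0.
#' @return List with `ec50` and `po_max`.
#' @export
recompose <- function(k_d, l_eq) {
  if (k_d <= 0 || l_eq <= 0)
    stop("k_d and l_eq must be positive", call. = FALSE)
  list(ec50 = k_d / (1 + l_eq), po_max = l_eq / (1 + l_eq))
}

#' Predict a Hill curve from a gating decomposition
#'
#' @param g A `gating_decomposition`.
#' @param hill_n Hill coefficient to use.
#' @param concentrations Micromolar concentrations.
#' @return Predicted normalized responses.
#' @export
predict_curve <- function(g, hill_n, concentrations) {
  stopifnot(inherits(g, "gating_decomposition"), hill_n > 0,
            all(concentrations >= 0))
  r <- recompose(g$k_d, g$l_eq)
  r$po_max * concentrations^hill_n /
    (concentrations^hill_n + r$ec50^hill_n)
}

#' Bootstrap uncertainty for the gating decomposition
#'
#' Nonparametric bootstrap over replicates within each concentration: each
#' resample refits the Hill equation and re-decomposes, giving empirical
#' standard errors for Kd and L that need no propagation formula.
#'
#' @param data Replicated dose-response data (as for [fit_hill()]).
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @return List with `se_k_d`, `se_l_eq`, `n_ok` (resamples that converged
#'   with Po_max < 1), and the resampled `k_d`/`l_eq` vectors.
#' @export
bootstrap_gating <- function(data, n_boot = 1000, seed = 1L) {
  split_idx <- split(seq_len(nrow(data)), data$concentration_uM)
  withr::with_seed(as.integer(seed), {
    kd <- le <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(split_idx, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      f <- try(suppressWarnings(fit_hill(data[idx, , drop = FALSE])),
               silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) next
      if (f$response_max <= 0 || f$response_max >= 1) next
      d <- decompose_gating(f$ec50, f$response_max)
      kd[b] <- d$k_d; le[b] <- d$l_eq
    }
    list(se_k_d = stats::sd(kd, na.rm = TRUE),
         se_l_eq = stats::sd(le, na.rm = TRUE),
         n_ok = sum(!is.na(kd)), k_d = kd, l_eq = le)
  })
}

#' Read a dose-response CSV in the interchange schema
#' @param path CSV with columns `ligand,genotype,concentration_uM,replicate,response`.
#' @return A tibble.
#' @export
read_dose_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("ligand", "genotype", "concentration_uM", "replicate", "response")
  if (!all(need %in% names(d)))
    stop("dose-response CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tibble::as_tibble(d)
}
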