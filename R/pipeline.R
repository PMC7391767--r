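#' Default analysis configuration
#'
#' Collects the constants the analyses run under: temperature for the
#' kT-to-kcal/mol conversion (297.15 K = 24 degrees C), single-channel dead
#' time (0.32 ms), coupling-energy specificity threshold (1.5 kT), emission
#' peak-shift detection limit (2 nm), bootstrap resamples, and the seed
#' recorded in every output.
#'
#' @param ... Named overrides of any default.
#' @return A `config_profile` list.
#' @export
default_config <- function(...) {
  cfg <- list(temperature = 297.15, dead_time = 0.32e-3,
              coupling_threshold_kT = 1.5, detection_limit_nm = 2,
              bootstrap_resamples = 1000, seed = 1L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  if (any(unlist(cfg[c("temperature", "dead_time", "coupling_threshold_kT",
                       "detection_limit_nm", "bootstrap_resamples")]) <= 0))
    stop("all configuration constants must be positive", call. = FALSE)
  structure(cfg, class = "config_profile")
}

#' Write / read a trace as raw little-endian float32 with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `sampling_rate_hz`, `units`, `seed`
#' and any ground truth, so a bare float array stays self-describing.
#'
#' @param trace A `simulated_trace` (or list with `samples`,
#'   `sampling_rate`).
#' @param path Output path for the float32 array.
#' @param truth Optional list stored under `truth` in the sidecar.
#' @return `path`, invisibly (writer); a list with `samples`,
#'   `sampling_rate`, `sidecar` (reader).
#' @export
write_trace_raw <- function(trace, path, truth = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(trace$samples), con, size = 4, endian = "little")
  sidecar <- list(sampling_rate_hz = trace$sampling_rate, units = "pA",
                  seed = trace$params$seed, truth = truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_raw
#' @export
read_trace_raw <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- file.size(path) / 4
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  list(samples = samples, sampling_rate = sidecar$sampling_rate_hz,
       sidecar = sidecar)
}

#' Generate a complete self-consistent synthetic study
#'
#' Writes to `out_dir` everything the full pipeline consumes, built around
#' the wild-type menthol behaviour (EC50 near 185 uM, Po_max near 0.81,
#' Hill coefficient 1.74) with a mutant cycle constructed to be specifically
#' coupled (the mutation raises the ligand Kd sixfold but leaves the analog
#' Kd unchanged, LnOmega = -ln 6 ~ -1.79), a four-mutant single-channel
#' series with Phi = 0.7, a 100-channel stationary patch at Po 0.81, and
#' three spectral pairs with shifts of +6.6, -2.5 and 0 nm. A `truth.json`
#' file carries every generating parameter.
#'
#' @param seed Integer master seed; per-file seeds are derived from it.
#' @param out_dir Writable directory (created if needed).
#' @param trace_duration Seconds of single-channel recording per mutant
#'   (default 100 s, about 2,000 dwell events at the wild-type rates).
#' @return The manifest list understood by [run_pipeline()], invisibly
#'   also written as `manifest.json`.
#' @export
make_demo_dataset <- function(seed, out_dir, trace_duration = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  # derive per-file seeds in double precision to stay inside 32-bit range
  sub_seed <- function(k)
    as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)

  # --- dose-response: WT/mutant x ligand/analog with a known cycle ------
  kd1 <- 975.8; l_wt_menthol <- 4.263         # WT + menthol
  kd2 <- kd1 * 6; l_mut_menthol <- 2.5        # mutant + menthol
  kd3 <- 1564; l_menthone <- 0.923            # WT + menthone
  kd4 <- kd3                                  # mutant + menthone: unchanged
  combos <- list(
    list(ligand = "menthol", genotype = "WT", k_d = kd1, l_eq = l_wt_menthol,
         hill_n = 1.74),
    list(ligand = "menthol", genotype = "mutant", k_d = kd2,
         l_eq = l_mut_menthol, hill_n = 1.74),
    list(ligand = "menthone", genotype = "WT", k_d = kd3,
         l_eq = l_menthone, hill_n = 1.5),
    list(ligand = "menthone", genotype = "mutant", k_d = kd4,
         l_eq = l_menthone, hill_n = 1.5))
  dose_files <- character(0)
  for (k in seq_along(combos)) {
    cb <- combos[[k]]
    ec50 <- cb$k_d / (1 + cb$l_eq)
    conc <- 10^seq(log10(ec50 / 10), log10(ec50 * 10), length.out = 8)
    ds <- simulate_dose_response(cb$k_d, cb$l_eq, cb$hill_n, conc,
                                 noise_sd = 0.02, n_replicates = 5,
                                 seed = sub_seed(k), ligand = cb$ligand,
                                 genotype = cb$genotype)
    f <- file.path(out_dir, sprintf("dose_%s_%s.csv", cb$ligand, cb$genotype))
    write_dose_csv(ds, f)
    dose_files <- c(dose_files, f)
  }

  # --- single-channel mutant series, Phi = 0.7 --------------------------
  series <- simulate_mutant_series(wt_opening = 50, wt_closing = 12.5,
                                   phi_true = 0.7,
                                   delta_log10_k = c(-0.6, -0.3, 0, 0.3),
                                   site = "demo_site", seed = sub_seed(10))
  trace_rows <- list()
  for (k in seq_len(nrow(series))) {
    tr <- simulate_two_state_trace(series$opening_rate[k],
                                   series$closing_rate[k],
                                   duration = trace_duration,
                                   sampling_rate = 10000, open_current = 1,
                                   noise_sd = 0.15, filter_cutoff = 2900,
                                   seed = sub_seed(20 + k))
    f <- file.path(out_dir, sprintf("trace_%s.f32", series$mutant[k]))
    write_trace_raw(tr, f, truth = list(opening_rate = series$opening_rate[k],
                                        closing_rate = series$closing_rate[k]))
    trace_rows[[k]] <- tibble::tibble(site = series$site[k],
                                      mutant = series$mutant[k],
                                      path = f, format = "raw")
  }
  traces <- do.call(rbind, trace_rows)

  # --- stationary macroscopic patch ------------------------------------
  patch_samples <- simulate_macroscopic_patch(100, 0.81, 1, 1e5,
                                              seed = sub_seed(40))
  patch_file <- file.path(out_dir, "patch.f32")
  write_trace_raw(list(samples = patch_samples, sampling_rate = 10000,
                       params = list(seed = sub_seed(40))),
                  patch_file, truth = list(n_channels = 100, p_open = 0.81,
                                           unitary_current = 1))

  # --- paired emission spectra, three sites ----------------------------
  shifts <- c(A = 6.6, B = -2.5, C = 0)
  spec_rows <- list()
  for (k in seq_along(shifts)) {
    site <- names(shifts)[k]
    ctrl <- simulate_emission_spectrum(peak = 480, width = 28, skew = 0.8,
                                       amplitude = 100, baseline = 5,
                                       noise_sd = 1,
                                       grid = seq(400, 620, by = 1),
                                       seed = sub_seed(50 + 2 * k))
    lig <- simulate_emission_spectrum(peak = 480 + shifts[[k]], width = 28,
                                      skew = 0.8, amplitude = 100,
                                      baseline = 5, noise_sd = 1,
                                      grid = seq(400, 620, by = 1),
                                      seed = sub_seed(51 + 2 * k))
    fc <- file.path(out_dir, sprintf("spectrum_%s_control.csv", site))
    fl <- file.path(out_dir, sprintf("spectrum_%s_menthol.csv", site))
    write_spectrum_csv(ctrl, fc)
    write_spectrum_csv(lig, fl)
    spec_rows[[k]] <- tibble::tibble(site = site, control = fc, ligand = fl)
  }
  spectra <- do.call(rbind, spec_rows)

  truth <- list(
    seed = seed,
    cycle = list(kd_wt_ligand = kd1, kd_mut_ligand = kd2,
                 kd_wt_analog = kd3, kd_mut_analog = kd4,
                 ln_omega = log(kd1 * kd4 / (kd2 * kd3))),
    gating = lapply(combos, function(cb)
      c(cb, list(ec50 = cb$k_d / (1 + cb$l_eq),
                 po_max = cb$l_eq / (1 + cb$l_eq)))),
    phi = list(site = "demo_site", phi_true = 0.7,
               wt_opening = 50, wt_closing = 12.5),
    patch = list(n_channels = 100, p_open = 0.81, unitary_current = 1),
    spectra = list(peak_control = 480, shifts = as.list(shifts)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(dose = list(files = dose_files, ligand = "menthol",
                               analog = "menthone"),
                   traces = traces,
                   patch = list(path = patch_file, unitary_current = 1),
                   spectra = spectra,
                   truth = file.path(out_dir, "truth.json"))
  # the on-disk manifest carries paths relative to out_dir so the dataset
  # is relocatable and byte-identical across runs
  rel <- function(p) sub(paste0("^", out_dir, "/?"), "", p)
  m_disk <- manifest
  m_disk$dose$files <- rel(m_disk$dose$files)
  m_disk$traces$path <- rel(m_disk$traces$path)
  m_disk$patch$path <- rel(m_disk$patch$path)
  m_disk$spectra$control <- rel(m_disk$spectra$control)
  m_disk$spectra$ligand <- rel(m_disk$spectra$ligand)
  m_disk$truth <- rel(m_disk$truth)
  jsonlite::write_json(m_disk, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a dataset manifest written by [make_demo_dataset()]
#'
#' Paths inside `manifest.json` are relative to its directory; this reader
#' resolves them so the result can be passed straight to [run_pipeline()].
#'
#' @param path Path to a `manifest.json`.
#' @return The manifest list with absolute-resolved paths.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  res <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  if (!is.null(m$dose)) m$dose$files <- res(m$dose$files)
  if (!is.null(m$traces)) {
    m$traces <- tibble::as_tibble(m$traces)
    m$traces$path <- res(m$traces$path)
  }
  if (!is.null(m$patch)) m$patch$path <- res(m$patch$path)
  if (!is.null(m$spectra)) {
    m$spectra <- tibble::as_tibble(m$spectra)
    m$spectra$control <- res(m$spectra$control)
    m$spectra$ligand <- res(m$spectra$ligand)
  }
  if (!is.null(m$truth)) m$truth <- res(m$truth)
  m
}

#' Run the full analysis pipeline over a manifest of input files
#'
#' Stages run in dependency order; a stage runs only when the manifest
#' provides its inputs, and a failing stage is recorded in `$errors`
#' without stopping the others. The stages are: Hill fits of every
#' dose-response file; gating decomposition (Kd, L) of every converged fit
#' with Po_max < 1; double-mutant-cycle coupling energies for every
#' non-wild-type genotype (using the manifest's `ligand` and `analog`
#' labels); single-channel idealization, rate estimation and per-site
#' Bronsted Phi fits over the trace table; stationary noise analysis of the
#' patch file; and paired-spectra shift classification.
#'
#' @param manifest List as produced by [make_demo_dataset()]: optional
#'   elements `dose` (list: `files`, `ligand`, `analog`), `traces`
#'   (data.frame: `site`, `mutant`, `path`, `format`), `patch` (list:
#'   `path`, `unitary_current`), `spectra` (data.frame: `site`, `control`,
#'   `ligand`).
#' @param config A `config_profile` (see [default_config()]).
#' @return A `report_bundle` list of tibbles: `hill`, `gating`, `coupling`,
#'   `rates`, `phi`, `noise`, `shifts`, plus `errors` and `provenance`.
#' @export
run_pipeline <- function(manifest, config = default_config()) {
  if (!length(manifest) ||
      !any(c("dose", "traces", "patch", "spectra") %in% names(manifest)))
    stop("manifest provides no inputs", call. = FALSE)
  bundle <- list(hill = NULL, gating = NULL, coupling = NULL, rates = NULL,
                 phi = NULL, noise = NULL, shifts = NULL,
                 errors = character(0),
                 provenance = list(config = unclass(config),
                                   inputs = manifest,
                                   package_version =
                                     as.character(utils::packageVersion("trpm8gating"))))
  note <- function(msg) bundle$errors <<- c(bundle$errors, msg)

  if (!is.null(manifest$dose)) {
    rows <- list()
    for (f in manifest$dose$files) {
      res <- try({
        d <- read_dose_csv(f)
        fit <- fit_hill(d)
        tibble::tibble(ligand = d$ligand[1], genotype = d$genotype[1],
                       ec50 = fit$ec50, hill_n = fit$hill_n,
                       response_max = fit$response_max,
                       se_ec50 = fit$se_ec50, rss = fit$rss,
                       converged = fit$converged)
      }, silent = TRUE)
      if (inherits(res, "try-error")) note(paste0("hill[", f, "]: ",
                                                  attr(res, "condition")$message))
      else rows <- c(rows, list(res))
    }
    if (length(rows)) bundle$hill <- do.call(rbind, rows)

    if (!is.null(bundle$hill)) {
      ok <- bundle$hill$converged & bundle$hill$response_max > 0 &
        bundle$hill$response_max < 1
      g <- bundle$hill[ok, , drop = FALSE]
      if (nrow(g)) {
        dec <- lapply(seq_len(nrow(g)), function(i)
          decompose_gating(g$ec50[i], g$response_max[i]))
        bundle$gating <- tibble::tibble(
          ligand = g$ligand, genotype = g$genotype, ec50 = g$ec50,
          po_max = g$response_max,
          k_d = vapply(dec, `[[`, numeric(1), "k_d"),
          l_eq = vapply(dec, `[[`, numeric(1), "l_eq"))
      }
      if (any(!ok)) note("gating: skipped fits with Po_max outside (0,1)")
    }

    lig <- manifest$dose$ligand %||% "menthol"
    ana <- manifest$dose$analog %||% NULL
    if (!is.null(bundle$gating) && !is.null(ana)) {
      gt <- bundle$gating
      muts <- setdiff(unique(gt$genotype), "WT")
      kd_of <- function(l, g) {
        v <- gt$k_d[gt$ligand == l & gt$genotype == g]
        if (length(v) == 1) v else NA_real_
      }
      rows <- list()
      for (m in muts) {
        kds <- c(kd_of(lig, "WT"), kd_of(lig, m), kd_of(ana, "WT"),
                 kd_of(ana, m))
        if (any(is.na(kds))) { note(paste0("coupling[", m,
                                           "]: incomplete cycle")); next }
        rows <- c(rows, list(tibble::tibble(
          mutant = m, kd_wt_ligand = kds[1], kd_mut_ligand = kds[2],
          kd_wt_analog = kds[3], kd_mut_analog = kds[4])))
      }
      if (length(rows))
        bundle$coupling <- coupling_table(do.call(rbind, rows),
                                          temperature = config$temperature,
                                          threshold_kT =
                                            config$coupling_threshold_kT)
    }
  }

  if (!is.null(manifest$traces)) {
    tr <- manifest$traces
    rows <- list()
    for (i in seq_len(nrow(tr))) {
      res <- try({
        raw <- if (identical(tr$format[i], "raw")) read_trace_raw(tr$path[i])
               else read_trace_csv(tr$path[i])
        lev <- detect_levels(raw$samples)
        rec <- idealize_half_amplitude(raw$samples, lev$baseline_mean,
                                       lev$open_mean,
                                       dead_time = config$dead_time,
                                       sampling_rate = raw$sampling_rate)
        kr <- estimate_rates(rec)
        tibble::tibble(site = tr$site[i], mutant = tr$mutant[i],
                       opening_rate = kr$opening_rate,
                       closing_rate = kr$closing_rate, k_eq = kr$k_eq,
                       p_open = open_probability(rec),
                       n_events = nrow(rec$events))
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        note(paste0("rates[", tr$path[i], "]: ",
                    attr(res, "condition")$message))
      else rows <- c(rows, list(res))
    }
    if (length(rows)) {
      bundle$rates <- do.call(rbind, rows)
      phi_rows <- lapply(unique(bundle$rates$site), function(s) {
        pts <- bundle$rates[bundle$rates$site == s, , drop = FALSE]
        pr <- try(fit_bronsted(pts), silent = TRUE)
        if (inherits(pr, "try-error")) { note(paste0("phi[", s, "]: ",
                                                     attr(pr, "condition")$message)); return(NULL) }
        tibble::tibble(site = s, phi = pr$phi, se_phi = pr$se_phi,
                       r_squared = pr$r_squared, n_mutants = pr$n)
      })
      phi_rows <- Filter(Negate(is.null), phi_rows)
      if (length(phi_rows)) bundle$phi <- do.call(rbind, phi_rows)
    }
  }

  if (!is.null(manifest$patch)) {
    res <- try({
      raw <- read_trace_raw(manifest$patch$path)
      ne <- noise_analysis(raw$samples, manifest$patch$unitary_current)
      tibble::tibble(n_channels = ne$n_channels, i_max = ne$i_max,
                     p_open = ne$p_open, mean_current = ne$mean_current,
                     variance = ne$variance, n_samples = ne$n_samples)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      note(paste0("noise: ", attr(res, "condition")$message))
    else bundle$noise <- res
  }

  if (!is.null(manifest$spectra)) {
    sp <- manifest$spectra
    pairs <- stats::setNames(lapply(seq_len(nrow(sp)), function(i)
      list(control = read_spectrum_csv(sp$control[i]),
           ligand = read_spectrum_csv(sp$ligand[i]))), sp$site)
    res <- try(batch_shift_table(pairs,
                                 detection_limit = config$detection_limit_nm),
               silent = TRUE)
    if (inherits(res, "try-error"))
      note(paste0("shifts: ", attr(res, "condition")$message))
    else bundle$shifts <- res
  }

  structure(bundle, class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a report bundle to CSV tables and a JSON summary
#'
#' One CSV per non-empty table (deterministic column order, numbers at
#' fixed precision) plus `report.json` holding the whole bundle. Exporting
#' the same bundle twice produces identical bytes.
#'
#' @param bundle A `report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param digits Significant digits for serialized numbers (default 10).
#' @return Character vector of files written.
#' @export
export_report <- function(bundle, out_dir, digits = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("hill", "gating", "coupling", "rates", "phi", "noise",
              "shifts")
  written <- character(0)
  for (tb in tables) {
    x <- bundle[[tb]]
    if (is.null(x)) next
    x <- as.data.frame(x)
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = digits)
    f <- file.path(out_dir, paste0(tb, ".csv"))
    utils::write.csv(x, f, row.names = FALSE)
    written <- c(written, f)
  }
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    lapply(bundle[tables], function(x) if (is.null(x)) NULL
           else as.data.frame(x)),
    f, auto_unbox = TRUE, digits = digits, null = "null")
  c(written, f)
}
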