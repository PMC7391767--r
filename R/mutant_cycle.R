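# CODATA 2018 constants; thermochemical calorie.
.kB <- 1.380649e-23      # J/K
.NA <- 6.02214076e23     # /mol
.J_PER_KCAL <- 4184

#' Non-additivity of a thermodynamic double-mutant cycle
#'
#' For the four corners of a mutant cycle — wild type and mutant channel,
#' each probed with the ligand and with its analog — the coupling parameter
#' is LnOmega = Ln\[(Kd_1 Kd_4) / (Kd_2 Kd_3)\], where Kd_1 is wild type +
#' ligand, Kd_2 mutant + ligand, Kd_3 wild type + analog, Kd_4 mutant +
#' analog. If the two perturbations act independently the fold-changes
#' cancel and LnOmega = 0; any residual measures the energetic coupling
#' between the perturbed ligand moiety and the mutated residue.
#'
#' @param kd_wt_ligand,kd_mut_ligand,kd_wt_analog,kd_mut_analog The four
#'   dissociation constants, all positive and in identical units.
#' @return Signed LnOmega (dimensionless).
#' @export
ln_omega <- function(kd_wt_ligand, kd_mut_ligand, kd_wt_analog,
                     kd_mut_analog) {
  kds <- c(kd_wt_ligand, kd_mut_ligand, kd_wt_analog, kd_mut_analog)
  if (any(!is.finite(kds)) || any(kds <= 0))
    stop("all four Kd values must be positive and finite", call. = FALSE)
  log((kd_wt_ligand * kd_mut_analog) / (kd_mut_ligand * kd_wt_analog))
}

#' Coupling energy from LnOmega
#'
#' The coupling energy is kT |LnOmega|; it is also reported in kcal/mol via
#' kB T NA / 4184 per kT. An energy above `threshold_kT` (1.5 kT by the
#' usual rule, about 0.89 kcal/mol at 24 degrees C) indicates a specific
#' interaction between the perturbed pair.
#'
#' @param ln_omega Signed LnOmega.
#' @param temperature Absolute temperature in kelvin (default 297.15 K,
#'   i.e. 24 degrees C).
#' @param threshold_kT Specificity threshold in kT multiples (strict
#'   inequality).
#' @return A `coupling_result` list: `ln_omega`, `energy_kT` (= |LnOmega|),
#'   `energy_kcal_mol`, `temperature`, `threshold_kT`, `is_specific`.
#' @export
coupling_energy <- function(ln_omega, temperature = 297.15,
                            threshold_kT = 1.5) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (threshold_kT < 0) stop("threshold must be non-negative", call. = FALSE)
  e_kT <- abs(ln_omega)
  e_kcal <- e_kT * .kB * temperature * .NA / .J_PER_KCAL
  structure(list(ln_omega = ln_omega, energy_kT = e_kT,
                 energy_kcal_mol = e_kcal, temperature = temperature,
                 threshold_kT = threshold_kT,
                 is_specific = e_kT > threshold_kT),
            class = "coupling_result")
}

#' Classify a coupling energy against the specificity threshold
#'
#' Strictly-greater-than comparison: an energy exactly at the threshold is
#' not called specific.
#'
#' @param result A `coupling_result`.
#' @param threshold_kT Threshold in kT multiples (default 1.5).
#' @return Logical flag.
#' @export
classify_specific <- function(result, threshold_kT = 1.5) {
  if (threshold_kT < 0) stop("threshold must be non-negative", call. = FALSE)
  result$energy_kT > threshold_kT
}

#' Coupling-energy table for a batch of mutant cycles
#'
#' @param cycles A data.frame with one row per mutant and columns
#'   `mutant`, `kd_wt_ligand`, `kd_mut_ligand`, `kd_wt_analog`,
#'   `kd_mut_analog`.
#' @param temperature Kelvin.
#' @param threshold_kT Specificity threshold.
#' @return Tibble with `mutant`, `ln_omega`, `energy_kT`, `energy_kcal_mol`,
#'   `specific`.
#' @export
coupling_table <- function(cycles, temperature = 297.15, threshold_kT = 1.5) {
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    lo <- ln_omega(cycles$kd_wt_ligand[i], cycles$kd_mut_ligand[i],
                   cycles$kd_wt_analog[i], cycles$kd_mut_analog[i])
    ce <- coupling_energy(lo, temperature, threshold_kT)
    tibble::tibble(mutant = cycles$mutant[i], ln_omega = ce$ln_omega,
                   energy_kT = ce$energy_kT,
                   energy_kcal_mol = ce$energy_kcal_mol,
                   specific = ce$is_specific)
  })
  do.call(rbind, rows)
}
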