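#!/usr/bin/env Rscript
# Generate the complete synthetic study every later stage consumes:
# dose-response tables for a wild-type/mutant x menthol/menthone cycle,
# a four-mutant single-channel series at Phi = 0.7, a 100-channel
# stationary patch at Po 0.81, and three paired ANAP-style spectra
# (+6.6, -2.5, 0 nm shifts). Ground truth is written to truth.json.

suppressPackageStartupMessages(library(trpm8gating))

seed <- 20260926L
out_dir <- "results/demo_data"
manifest <- make_demo_dataset(seed, out_dir)

truth <- jsonlite::read_json(manifest$truth, simplifyVector = TRUE)
cat("Synthetic study written to", out_dir, "under seed", seed, "\n")
cat("  dose-response files:", length(manifest$dose$files), "\n")
cat("  constructed cycle LnOmega:", round(truth$cycle$ln_omega, 3), "\n")
cat("  Phi series truth:", truth$phi$phi_true, "\n")
cat("  patch: N =", truth$patch$n_channels, ", Po =", truth$patch$p_open, "\n")
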