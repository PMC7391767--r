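#!/usr/bin/env Rscript
# ANAP emission spectra: fit each paired spectrum with the mode-
# parameterized skewed Gaussian, compute the ligand-induced peak shift per
# site, and classify against the 2 nm detection limit.
# Writes results/shifts.csv.

suppressPackageStartupMessages(library(trpm8gating))

manifest <- read_manifest("results/demo_data/manifest.json")
bundle <- run_pipeline(list(spectra = manifest$spectra))
invisible(export_report(bundle, "results"))

cat("Peak shifts (ligand - control), 2 nm detection limit:\n")
print(as.data.frame(bundle$shifts[, c("site", "peak_control", "peak_ligand",
                                      "delta_peak", "classification")]),
      digits = 5)
cat("sites were generated with shifts +6.6, -2.5 and 0 nm\n")
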