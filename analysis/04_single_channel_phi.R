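#!/usr/bin/env Rscript
# Single-channel kinetics: idealize each mutant recording by the
# half-amplitude method with a 0.32 ms dead time, estimate opening and
# closing rates, and fit the Bronsted plot to obtain the Phi value for the
# site. Writes results/rates.csv and results/phi.csv.

suppressPackageStartupMessages(library(trpm8gating))

manifest <- read_manifest("results/demo_data/manifest.json")
bundle <- run_pipeline(list(traces = manifest$traces))
invisible(export_report(bundle, "results"))

cat("Per-mutant rates (events after dead-time imposition):\n")
print(as.data.frame(bundle$rates), digits = 4)
cat(sprintf("\nBronsted slope: Phi = %.2f +/- %.2f (R^2 = %.3f, %d mutants)\n",
            bundle$phi$phi, bundle$phi$se_phi, bundle$phi$r_squared,
            bundle$phi$n_mutants))
cat("series was generated with Phi = 0.7\n")
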