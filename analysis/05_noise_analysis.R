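#!/usr/bin/env Rscript
# Stationary noise analysis of the macroscopic patch: estimate channel
# count N = I^2/(iI - sigma^2), the maximum current N*i, and the open
# probability I/(N*i). Writes results/noise.csv.

suppressPackageStartupMessages(library(trpm8gating))

manifest <- read_manifest("results/demo_data/manifest.json")
bundle <- run_pipeline(list(patch = manifest$patch))
invisible(export_report(bundle, "results"))

ne <- bundle$noise
cat(sprintf("I = %.2f pA, sigma^2 = %.2f pA^2, i = %g pA\n",
            ne$mean_current, ne$variance, manifest$patch$unitary_current))
cat(sprintf("-> N = %.1f channels, Imax = %.1f pA, Po = %.3f\n",
            ne$n_channels, ne$i_max, ne$p_open))
cat("patch was generated with N = 100, Po = 0.81\n")
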