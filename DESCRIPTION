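Package: trpm8gating
Title: Ligand-Gating Analysis of Menthol Activation of TRPM8
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for dissecting how menthol binds and activates
    the cold receptor TRPM8 from electrophysiology and fluorescence data:
    Hill fits of concentration-response curves decomposed into binding (Kd)
    and gating (L) equilibria under a C0 <-> C1 <-> O scheme, thermodynamic
    double-mutant-cycle coupling energies with the 1.5 kT specificity rule,
    stationary noise analysis of macroscopic currents (channel count N and
    open probability), half-amplitude single-channel idealization with dead
    time and two-state rate estimation, Bronsted (rate-equilibrium) Phi
    analysis across mutant series, and skewed-Gaussian fitting of ANAP
    emission spectra with peak-shift classification. A seeded synthetic-data
    module generates every input class (two-state stochastic gating traces,
    binomial multichannel patches, Hill dose-response tables, collinear
    mutant rate series, skewed emission spectra) with ground truth attached.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
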