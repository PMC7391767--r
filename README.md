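# trpm8gating

Quantitative analysis of how the cooling agent menthol binds and activates
the cold-receptor ion channel TRPM8, built for electrophysiologists and
channel biophysicists who want the full chain — from dose–response curves
and single-channel recordings to coupling energetics and fluorescence peak
shifts — as tested, reusable R functions rather than spreadsheet steps.

## The models at the core

**Ligand-gating decomposition.** Menthol is a partial agonist
(P<sub>o,max</sub> ≈ 0.81 at saturation), which makes the minimal scheme

&nbsp;&nbsp;&nbsp;&nbsp;C₀ ⇌(K_d) C₁ ⇌(L) O

identifiable from one Hill fit: EC₅₀ = K_d/(1+L) and P<sub>o,max</sub> =
L/(1+L), so `decompose_gating()` separates a mutation's effect on binding
(K_d) from its effect on gating (L).

**Double-mutant-cycle coupling.** For wild-type/mutant × ligand/analog,
LnΩ = Ln[(K<sub>d,1</sub>·K<sub>d,4</sub>)/(K<sub>d,2</sub>·K<sub>d,3</sub>)];
the coupling energy |LnΩ|·kT exceeds 1.5 kT (0.89 kcal/mol at 24 °C) only
for a specific residue–moiety interaction.

**Single-channel kinetics and Φ analysis.** Traces are idealized by the
half-amplitude method with a 0.32 ms dead time; two-state rates are
reciprocal mean dwells (the exponential MLE); across mutants at one site,
Φ is the Brønsted slope of log₁₀(opening rate) vs log₁₀(K), ordering
residues along the activation pathway.

**Stationary noise analysis.** N = I²/(i·I − σ²) gives the channel count of
a macroscopic patch from its mean and variance; P_o = I/(N·i).

**ANAP spectra.** Emission bands are fitted with a skewed Gaussian
(exponentially modified Gaussian parameterized by its mode), and
ligand-induced peak shifts beyond a 2 nm detection limit are classified
redshift/blueshift.

A seeded synthetic-data module (`simulate_*`) generates every input class —
Gillespie two-state traces with recording noise and 2.9 kHz filtering,
binomial multichannel patches, Hill dose–response tables, exactly collinear
mutant rate series, skewed spectra — each carrying its ground truth, so the
whole chain is testable without raw recordings.

## Worked example

```r
library(trpm8gating)

# wild-type menthol: printed whole-cell parameters -> binding and gating
d <- decompose_gating(ec50 = 185.4, po_max = 0.81)
c(kd = d$k_d, L = d$l_eq)
#>          kd           L
#> 975.789474    4.263158

# a sixfold Kd increase confined to the ligand arm of the cycle
lnO <- ln_omega(975.8, 975.8 * 6, 1564, 1564)
coupling_energy(lnO, temperature = 297.15)[c("energy_kT", "energy_kcal_mol", "is_specific")]
#> $energy_kT
#> [1] 1.791759
#> $energy_kcal_mol
#> [1] 1.05803
#> $is_specific
#> [1] TRUE

# single-channel rates from a simulated recording
tr  <- simulate_two_state_trace(50, 12.5, duration = 100, seed = 7)
lev <- detect_levels(tr$samples)
rec <- idealize_half_amplitude(tr, lev$baseline_mean, lev$open_mean,
                               dead_time = 0.32e-3)
kr  <- estimate_rates(rec)
round(c(beta = kr$opening_rate, alpha = kr$closing_rate,
        po = open_probability(rec)), 2)
#>  beta alpha    po
#> 47.89 12.37  0.79

# stationary noise analysis of a 100-channel patch
x <- simulate_macroscopic_patch(100, 0.81, 1, 1e5, seed = 11)
ne <- noise_analysis(x, unitary_current = 1)
round(c(N = ne$n_channels, po = ne$p_open), 2)
#>      N     po
#> 100.13   0.81
```

The interpretation: the decomposition says menthol binds wild-type TRPM8
with K_d ≈ 976 µM while gating amplifies its apparent potency to an EC₅₀ of
185 µM; a 1.79 kT coupling energy flags the perturbed pair as specifically
interacting; the simulated recording returns the generating rates (50/s,
12.5/s) within sampling error, and the noise analysis recovers the patch's
100 channels at P_o 0.81.

## Analysis workflow

`analysis/01_simulate_study.R` … `06_anap_spectra.R` run the stages in
order on a generated study (dose–response cycle, Φ site, patch, spectral
pairs), narrating what each finds and writing tidy tables under `results/`.
Each is a thin driver over the package functions:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_dose_response.R
# ... through 06
```

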