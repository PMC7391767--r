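---
title: "Dissecting ligand gating of TRPM8: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting ligand gating of TRPM8: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpm8gating)
```

This vignette explains the models behind each stage of the package, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the choices we made where the design was genuinely open.

## The gating scheme and its decomposition

Menthol is a partial agonist of TRPM8: even at saturating concentration the
maximum open probability stays well below one (around 0.81 in whole-cell
measurements). That makes the minimal linear scheme

$$C_0 \overset{K_d}{\leftrightarrow} C_1 \overset{L}{\leftrightarrow} O$$

identifiable from a single dose–response curve: with binding governed by the
dissociation constant $K_d$ (µM) and the final closed-to-open transition by
the equilibrium constant $L$ (dimensionless), the apparent Hill parameters
are

$$\mathrm{EC}_{50} = \frac{K_d}{1+L}, \qquad
  P_{o,\max} = \frac{L}{1+L}.$$

`decompose_gating()` inverts these exactly: $L = P_{o,\max}/(1-P_{o,\max})$,
$K_d = \mathrm{EC}_{50}(1+L)$. The inversion degenerates as
$P_{o,\max} \to 1$ (a full agonist carries no information about $L$), so the
function refuses $P_{o,\max} \ge 1$ rather than extrapolating. Two
consequences are worth internalizing: $\mathrm{EC}_{50} < K_d$ always
(favourable gating makes a ligand look more potent than its binding), and
the decomposition inherits the uncertainty of both Hill parameters — which
is why `bootstrap_gating()` resamples replicates within each concentration
and refits, rather than applying a delta-method formula to a single fit
(the closed-form propagation is available too, but the bootstrap makes no
local-linearity assumption near $P_{o,\max} \to 1$ where the transformation
is strongly nonlinear).

`fit_hill()` fits $R_{\max} c^{n}/(c^{n} + \mathrm{EC}_{50}^{n})$ to all
replicate points by Levenberg–Marquardt least squares. Hill fits on steep
curves have genuine local minima, so the fit is multi-started: EC50 from the
geometric mean of the tested concentrations and from the concentration whose
mean response is nearest half-max, $n \in \{1, 2\}$. Ties resolve to the
lowest residual sum of squares, then the smaller EC50. The Hill coefficient
is refit per curve rather than shared across genotypes; sharing would borrow
strength but assumes mutations leave cooperativity untouched, which is
exactly what the mutants under study may violate.

## Double-mutant-cycle coupling

For the four corners wild-type/mutant × ligand/analog, non-additivity of the
binding free energies is

$$\ln\Omega = \ln\frac{K_{d,1} \cdot K_{d,4}}{K_{d,2} \cdot K_{d,3}},$$

with the coupling energy $|\ln\Omega| \cdot kT$. Energies above $1.5\,kT$
(0.89 kcal/mol at 24 °C) indicate a specific interaction between the
perturbed ligand moiety and the mutated residue; the comparison is strict
(`energy_kT > threshold`), so a value exactly at the threshold is not called
specific. Conversions use CODATA 2018 constants and the thermochemical
calorie (4184 J). Temperature is always an explicit argument with default
297.15 K (24 °C, the conventional conversion temperature); recordings in
this kind of experiment are usually at 22 °C, and both are legitimate — the
kcal/mol value shifts by under 1%. The cycle is computed on $K_d$, not on
$L$: coupling on the gating constant conflates binding-site energetics with
downstream conformational coupling. The classification reports the energy
magnitude (bar-plot convention) but retains signed $\ln\Omega$, since the
sign distinguishes cooperative from antagonistic coupling.

## Single-channel idealization and rates

Traces are idealized by the half-amplitude method: threshold at the midpoint
of the baseline and open levels (located by `detect_levels()` from the
all-point amplitude histogram, two dominant modes refined by a local
Gaussian/parabolic fit on log counts), each sample assigned to the side of
the threshold it falls on, runs of equal state becoming dwell events.
Samples exactly at threshold keep the previous sample's state — a
deterministic, hysteresis-free tie-break; the leading sample defaults to
closed, matching the resting channel.

A dead time (default 0.32 ms) is then imposed retrospectively: every
interior event shorter than the dead time is merged into its predecessor and
same-state neighbours are coalesced, iterating until stable. Merging into
the predecessor is the standard retrospective rule — the alternative
(splitting between neighbours) changes dwell means negligibly but breaks the
idempotence property we test. The first and last events are never merged
away: they are duration-censored by the record boundary, flagged as edge
events, and excluded from all dwell averages.

For a two-state channel, dwell durations are exponential, so the maximum-
likelihood rates are reciprocal mean dwells: opening rate $= 1/\bar t_c$,
closing rate $= 1/\bar t_o$, each with standard error rate$/\sqrt{n}$, and
$K = \beta/\alpha$. Dead-time imposition biases rates upward because short
events are unobserved; we deliberately do not correct for this by default
(the experimental convention this mirrors reports uncorrected rates), but
`estimate_rates(..., dead_time_correction = TRUE)` subtracts the dead time
from each dwell before averaging — the exact first-order correction for
left-truncated exponentials. At the rates used throughout (tens per second
against a 0.32 ms dead time) the bias is a few percent.

## Brønsted (Φ) analysis

Across mutants at one site, the Φ value is the ordinary least-squares slope
of $\log_{10}\beta$ on $\log_{10}K$. Φ near 1 means mutations perturb mostly
the opening rate (the residue's environment changes early along the
activation pathway, in the single-pathway reading); Φ near 0, mostly the
closing rate (late movement). The regression is unweighted, matching how
such plots are conventionally fitted with 3–5 mutants; per-point weighting
by rate standard errors is possible but with so few points mostly reshuffles
leverage. At least 3 mutants and distinct $K$ values are required. The
parallel-pathway reading of Φ (as a pathway probability) is interpretive and
deliberately not encoded in any computation.

`simulate_mutant_series()` constructs rate sets that are *exactly* collinear
— $\log_{10}\beta = \log_{10}\beta_{wt} + \Phi\,\Delta\log_{10}K$,
$\log_{10}\alpha = \log_{10}\alpha_{wt} - (1-\Phi)\,\Delta\log_{10}K$ — so
slope recovery is testable to machine precision separately from the
stochastic error introduced when rates are re-estimated from simulated
recordings.

## Stationary noise analysis

For $N$ identical independent channels at open probability $P_o$ with
unitary current $i$, the steady-state current has mean $I = N i P_o$ and
variance $\sigma^2 = N i^2 P_o(1-P_o)$; eliminating $P_o$,

$$N = \frac{I^2}{iI - \sigma^2}, \qquad
  P_o = \frac{I}{N i}.$$

The estimator is exact on binomial moments (an algebraic identity, which the
tests exploit) and degrades in a known direction: any extra instrumentation
variance inflates $\sigma^2$ and biases $N$ upward, so an optional
`background_variance` can be subtracted. $i$ is an input, not estimated from
a variance–mean parabola — it is measured separately from single-channel
amplitudes, and nonstationary ensemble analysis is out of scope. $N$ is
reported as a real number; rounding belongs in reports. Stationarity of the
analysed segment is the user's responsibility: window selection is an
explicit input, never guessed.

## Emission spectra and peak shifts

Fluorescence emission bands are asymmetric, with a heavier red tail. We
model them as an exponentially modified Gaussian (Gaussian of width σ
convolved with a one-sided exponential of scale $|s|\sigma$, mirrored for
negative $s$), *reparameterized so the reported "peak" is the mode of the
curve*, located numerically and normalized to unit height. The mode — not
the EMG mean, which is pulled into the tail — is what one reads off a
spectrum as the emission maximum, and parameterizing by it makes the fitted
`peak` directly comparable between conditions. Since only "a skewed
Gaussian" is conventionally specified for such fits and commercial packages
differ in their exact form, equivalence is asserted only against this
package's own generator; a mode is far less form-sensitive than tail
parameters, which is precisely why shifts are computed on modes.

`fit_skewed_gauss()` runs a symmetric-Gaussian candidate (skew fixed at 0)
plus EMG starts at skew ∈ {0.3, −0.3, 1}, keeping the lowest residual sum of
squares — so exactly symmetric spectra are recovered without skew-induced
peak bias. Shifts (ligand − control) beyond a 2 nm detection limit are
classified redshift/blueshift; within it, "no-change". The limit reflects a
typical imaging-system resolution and is an explicit parameter. Shifts at
exactly the limit are boundary cases where noise decides the call; the tests
accept either outcome there.

## The synthetic-data generators

The generators define the study conditions everything is validated under:

- **Two-state traces**: Gillespie dwell sequences (exponential dwells at the
  stated rates, starting closed — a resting channel; overridable), rendered
  by point sampling at 10 kHz, 1 pA unitary current, Gaussian noise of
  0.15 pA s.d., and a Gaussian low-pass filter with −3 dB at 2.9 kHz —
  matching common patch-clamp acquisition settings. The Gaussian kernel
  approximates the Bessel-like response of patch amplifiers without a
  filter-design dependency; its time-domain s.d. is
  $\sqrt{\ln 2}/(2\pi f_c)$. Noise magnitude and filter order beyond the
  cutoff are free parameters of the emulation; 0.15 pA on a 1 pA opening is
  a realistic signal-to-noise for a good patch. Point sampling means
  sub-sample dwells can vanish from the samples while remaining in the
  ground-truth list — exactly the resolution loss real digitization causes.
- **Macroscopic patches**: i.i.d. binomial draws — ideal stationarity, no
  drift, no 1/f noise. Passing the noise-analysis tests therefore shows the
  estimator is correct, not that real patches are stationary.
- **Dose–response**: Hill means from $(K_d, L, n_H)$ with additive Gaussian
  replicate noise truncated at zero (responses are non-negative); s.d. 0.02
  on the normalized scale with 5 replicates and 8 concentrations spanning
  0.1–10× EC50 — a deliberately clean version of whole-cell variability,
  which in practice also has between-cell scale error.
- **Spectra**: EMG profile plus baseline and Gaussian noise at 1% of
  amplitude on a 1 nm grid over 400–620 nm.
- **Demo study**: wild-type menthol behaviour at $K_d$ 975.8 µM, $L$ 4.263
  ($\mathrm{EC}_{50}$ 185.4 µM, $P_{o,\max}$ 0.81), $n_H$ 1.74; menthone at
  $K_d$ 1564 µM, $L$ 0.923; the mutant raises the menthol $K_d$ sixfold and
  leaves the analog unchanged, giving $\ln\Omega = -\ln 6 \approx -1.79$ — a
  specifically coupled pair; a Φ = 0.7 site with ΔlogK ∈ {−0.6, −0.3, 0,
  0.3} around rates 50/s and 12.5/s; a 100-channel patch at $P_o$ 0.81;
  spectral shifts +6.6, −2.5, 0 nm.

Every generator is bit-reproducible under its seed (`withr::with_seed`, so
the caller's RNG stream is untouched).

## Numerical choices and degenerate inputs

- Event boundaries falling exactly on sample instants take the *new* state
  (left-closed intervals), consistently in simulation and re-rendering;
  idempotence of idealization then holds up to one-sample requantization.
- A dead time shorter than one sample period cannot remove anything a
  threshold crossing created; it warns and performs no merging.
- All-zero responses, flat spectra, unimodal amplitude histograms, and
  empty manifests produce explicit errors ("no activation", "no peak",
  "one level", validation error) rather than silent defaults; Hill and
  spectral fits carry an honest `converged` flag.
- Variance above the binomial bound ($iI \le \sigma^2$) makes $N$
  undefined and errors; $P_o$ up to 2% above 1 is clipped (sampling
  slack), beyond that it errors as an inconsistency.
- EMG evaluation works on the log scale through `pnorm(..., log.p = TRUE)`
  to avoid overflow of the $\exp \cdot \mathrm{erfc}$ product at large
  skew.

## Problem sizes used in validation

The test suite and acceptance script validate at sizes chosen to put
statistical bounds several standard errors out while staying desk-scale:
single-channel recordings of 100 s at 10 kHz (about 2,000 dwell events at
the wild-type rates), 50-seed repeats for rate/Po/N recovery, 200 noisy
dose–response curves for EC50 recovery, $10^5$-sample patches, and 20-seed
spectral fits. These sizes are the package's own validation choices and are
stated here so they can be scaled in either direction knowingly.

## Known limitations

- The kinetic model is strictly two-state; bursting, multiple open states,
  or aggregated Markov schemes with hidden states are out of scope, as is
  hidden-Markov idealization.
- Missed-event correction is first-order only and off by default.
- The noise-analysis estimator assumes identical independent channels and
  true stationarity; no nonstationary ensemble analysis is provided.
- Spectral fits assume a single emission band; overlapping bands need a
  mixture model this package does not implement.
- The synthetic data are idealized as listed above, so green tests
  demonstrate estimator correctness under the stated conditions, not
  robustness to every pathology of real recordings.
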