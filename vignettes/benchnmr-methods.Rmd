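---
title: "Benchtop versus high-field NMR metabolomics: models and methods"
author: "benchnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchtop versus high-field NMR metabolomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benchnmr)
```

## The scientific problem

Benchtop NMR spectrometers (permanent magnets, ~60 MHz proton frequency)
cost a fraction of superconducting high-field systems and need no
cryogens, which makes them candidates for point-of-care metabolomics.
The price is resolution. A chemical shift difference of $\Delta\delta$
ppm corresponds to $\Delta\delta \times \nu_0$ Hz at spectrometer
frequency $\nu_0$ (MHz), while scalar couplings $J$ are fixed in Hz.
On the ppm axis a multiplet of $n$ lines therefore occupies roughly

$$ w = \frac{n \cdot J}{\nu_0} \ \mathrm{ppm}, $$

thirteen times wider at 60 MHz than at 800 MHz: the propionate CH$_3$
triplet ($J = 7.70$ Hz) spans 0.385 ppm at 60 MHz versus 0.029 ppm at
800 MHz, and the valine/isoleucine CH$_3$ doublets ($J = 7.05$ Hz)
envelop 0.235 ppm. Note this package deliberately implements the
multiplicity-times-$J$ convention ($n\cdot J/\nu_0$), not the
peak-to-peak span $(n-1)\cdot J/\nu_0$; the two differ by one
$J/\nu_0$, and `multiplet_envelope_ppm()` documents the choice.
Overlap, not sensitivity, is the dominant failure mode of low-field
fecal metabolomics, and every analysis stage in this package exists to
measure, work around, or exploit that fact.

The package simulates a two-group murine colitis study — control versus
DSS-treated, 3 subjects per group, fecal extracts sampled on days 0–5
(36 samples), measured at both 60 and 800 MHz — and carries the spectra
through binning, multivariate discrimination, and acetate
quantification with known ground truth.

## Spin simulation

`first_order_peaks()` implements the weak-coupling (first-order)
multiplet construction: each group of $n_g$ equivalent protons at shift
$\delta_g$ is split by every coupled partner group of $n_j$ protons
into $n_j + 1$ lines with binomial intensities, positions
$\delta_g \pm k J / \nu_0$. Intensities sum to $n_g$ — integrated
intensity is field-independent, which the test suite asserts at both
fields for every library entry.

`full_hamiltonian_peaks()` builds the isotropic liquid-state spin
Hamiltonian in Hz,

$$ H = \sum_i \nu_i I_{z,i} + \sum_{i<j} J_{ij}\,
       \mathbf{I}_i\!\cdot\!\mathbf{I}_j, $$

diagonalizes it, and computes single-quantum transition intensities
from the squared transverse transition moment, normalized so the total
equals the proton count. This reproduces second-order (strong-coupling)
features — the AB "roof" effect prominent at 60 MHz — exactly: the
two-spin case is checked against the closed-form AB quartet to 1e-9,
and the $\Delta\nu \gg J$ limit against the first-order construction.
Equivalent groups are expanded into explicit spins with identical
shifts; the $2^N$ state space is capped at 8 spins, beyond which the
function raises an error directing callers to the first-order mode
(glucose and TSP exceed the cap). Couplings within an equivalent group
do not affect the spectrum and are skipped.

**Lineshape.** Rendered lines are area-normalized pseudo-Voigt
profiles, $\eta G + (1-\eta) L$ with default $\eta = 0.1$, FWHM 1.4 Hz
at 60 MHz and 1.0 Hz at 800 MHz. No published linewidths exist for the
emulated instruments; these values reproduce the qualitative congestion
of benchtop fecal spectra and the homogeneity gap between magnet
classes. Noise is i.i.d. Gaussian in the frequency domain; the only
time-domain noise treatment is in the FID round-trip tests.

**Grid.** The default axis is −0.5 to 10.5 ppm with 32,768 points at
60 MHz and 65,536 at 800 MHz (typical time-domain sizes). The
half-ppm margin beyond the 0–10 ppm analysis window keeps the TSP
reference singlet at 0.0 ppm — and its integration window — fully on
the axis; an axis that starts exactly at 0 truncates half the reference
peak. Axes are stored ascending; plots reverse the axis per NMR
convention.

## The synthetic cohort

`cohort_design()` reads a YAML design whose defaults encode the study
conditions: 2 groups × 3 subjects × days 0–5, internal standards TSP
0.5 mM and a 1 mM formate spike, biological coefficient of variation
20%, and per-metabolite day-5 fold changes in the colitis direction
(acetate ×2.0, succinate ×1.8, glucose and taurine ×1.3, butyrate
×0.5, propionate / branched-chain amino acids / leucine / alanine /
aspartate / glycerol / threonine ×0.7). Concentrations are lognormal
with moment-matched parameters (arithmetic mean = target, sd/mean =
CV), which guarantees positivity.

**Effect schedule.** Fold changes follow a saturating ramp
$f(d) = f_5^{\sqrt{(d - d_0 + 1)/(5 - d_0 + 1)}}$ from onset day
$d_0 = 2$: no effect through day 1, a partial effect on day 2, most of
the shift by days 3–4, the full fold at day 5. The shape was chosen so
the treated group's multivariate signature separates partially at day 2
and completely from day 3 on — the qualitative time course the design
emulates; a linear log-fold ramp leaves day-3 samples inside the
control score cloud too often to reproduce that pattern. Fold
magnitudes themselves are free parameters of the generator (the
emulated study reports directions, not sizes) and live in the design
file, not in code.

**Rendering.** Because concentrations enter linearly, each sample is a
concentration-weighted sum of per-metabolite unit-concentration
spectra rendered once per field and cached, plus per-sample noise
scaled so the strongest line of the mean control profile has peak SNR
300. Chemical shifts do not vary between samples, and no broad fecal
background hump is added by default — two features of real data the
generator does not emulate, so passing tests demonstrate correctness of
the pipeline's arithmetic, not robustness to shift drift or matrix
effects. Samples are independent draws; within-subject correlation
across days is not modeled. The default simulation mode is first-order
(strong-coupling rendering is available per metabolite up to the spin
cap); at 60 MHz this understates second-order distortion of the
crowded 0.9–1.1 ppm region.

## Processing

`apodize_and_transform()` multiplies the FID by
$\exp(-\pi\,\mathrm{lb}\,t)$ (so `lb` adds directly to the Lorentzian
FWHM in Hz; default 0.2 Hz) and Fourier-transforms to a ppm axis about
the carrier. `phase_correct()` offers manual angles and an automated
mode that minimizes the sum of squared negative intensities — the
emulated workflow phased manually, so the automated objective is an
approximation and is flagged in the output metadata. A coarse
$\varphi_0$ scan precedes the simplex refinement to avoid the
sign-flipped local optimum. `baseline_correct()` fits a low-order
polynomial (default degree 3) by iteratively reweighted least squares,
down-weighting points more than $2\sigma$ above the running fit so the
polynomial tracks signal-free regions.

`reference_and_normalize()` shifts the axis so the TSP maximum (sought
within ±0.3 ppm of 0) sits at exactly 0.000 ppm, then divides by the
TSP integral over ±0.05 ppm. The ±0.05 ppm window covers the singlet
plus its 60 MHz broadening; "TSP peak area" has no standard
definition, so the window is configurable. The operation is idempotent
and scale-invariant, and refuses spectra with no peak above 5× noise in
the search window. Because the window captures a smaller fraction of
the broader 60 MHz TSP line than of the 800 MHz one, normalized areas
carry a small field-dependent scale factor — which is why all
quantification goes through per-field calibration curves rather than
raw stoichiometry.

## Binning

`binning_scheme()` tiles half-open 0.04 ppm bins over 0–10 ppm (0 edge
inclusive, 10 exclusive) and drops bins whose *center* falls in an
exclusion window, by default the residual-water region 4.5–5.0 ppm.
Since neither 4.5 nor 5.0 is a multiple of 0.04, the center rule drops
exactly the 13 bins starting at 4.48 through 4.96, leaving 237; an
"any-overlap" rule is available for the stricter reading. Bin values
are trapezoidal areas, not mean intensities — areas are what TSP
normalization preserves. Only uniform-width binning is supported:
adaptive schemes are out of scope because the emulated analysis found
bin-width changes immaterial.

## Multivariate analysis

`scale_columns()` implements Pareto ($x \mapsto (x-\bar x)/\sqrt{s}$),
unit-variance, and centering-only scaling; zero-variance bins are
centered only and reported. `fit_pca()` is NIPALS with deflation
(convergence 1e-12, up to 20,000 iterations — cheap on bin matrices
and necessary when leading eigenvalues nearly tie), checked against an
SVD oracle up to sign.

`fit_oplsda()` implements two-class O-PLS: `n_ortho` orthogonal
components (default 1, the typical choice for a two-class model) are
split off by deflating the orthogonal part of the loading against the
y-predictive weight, then a single predictive PLS component is fitted.
The class vector is coded ±1 and centered; the predictive component is
oriented so the treated-class mean score is positive, making S-line
signs reproducible. Diagnostics: R2X (fraction of X sum of squares in
all components), R2Y (fraction of y variance captured), and Q2
$= 1 - \mathrm{PRESS}/\mathrm{SS}$ from 7-fold cross-validation with
deterministic venetian-blind fold assignment in row order (sample $i$
to fold $(i-1) \bmod 7 + 1$) — reproducible without randomness, and
order-invariance given a fixed fold vector is tested. Cross-validation
refits on row subsets of the already-scaled matrix; fold-wise
re-scaling is not performed, a simplification relative to full
double-cross-validation. VIP for the single predictive component is
$\sqrt{p}\,|w_j|/\lVert w\rVert$, so mean-square VIP is 1 and
$\sum_j \mathrm{VIP}_j^2 = p$ exactly; `VIP > 1` is exposed as the
conventional selection filter. The S-line reports per-bin covariance
(magnitude) and Pearson correlation (color) with the predictive score.

The emulated study is ambiguous about whether day 2 belongs in the
"post-onset" PCA (its text says days 0–2 were excluded; its figure
says days 2–5). Both subsets are supported through
`run_config(days_multivariate = ...)`; the default is days 2–5,
matching the figure and giving the onset day a vote in the model.

## Quantification

Three strategies estimate acetate (singlet, 1.92 ppm) from
TSP-normalized spectra:

1. **Region integration** (`integrate_region()`): trapezoidal integral
   over a fixed window — 1.80–2.04 ppm at 60 MHz (the singlet plus the
   shoulders that broaden into it), 1.90–1.94 ppm at 800 MHz. Every
   neighbouring multiplet that leaks into the window is counted; at
   60 MHz the glutamate and leucine multiplets do, making this the
   noisiest method by construction.
2. **Generalized-Lorentzian fitting** (`fit_gl_peak()`): nonlinear
   least squares of one target peak plus up to two nuisance peaks and a
   linear local baseline. The "generalized Lorentzian" of the emulated
   software is proprietary and undocumented; it is interpreted here as
   an area-parameterized pseudo-Voigt with free mixing $\eta \in [0,1]$
   (an optional kurtosis generalization was considered and dropped —
   $\eta$ alone already spans the Lorentzian–Gaussian family the data
   need). The analytic area recovers tail mass outside the window,
   the central advantage over region integration. Convergence:
   relative residual change below 1e-10 or 500 Levenberg–Marquardt
   iterations; a fit whose target center migrates to the window
   boundary is an error, not a result.
3. **Library fitting** (`library_fit()`): non-negative least squares of
   per-mM metabolite templates (rendered with a lineshape pre-calibrated
   on the observed TSP signal) plus an unconstrained linear baseline.
   Templates whose peaks lie outside the fit window are excluded and
   reported as zero rather than estimated from their tails.

All three responses are converted to mM through per-field calibration
curves (`acetate_calibration()`, `build_calibration()`): simulated
2–20 mM sodium-acetate standards in triplicate, ordinary least squares
with intercept. Calibration noise defaults to peak SNR 500 at 60 MHz
and 5000 at 800 MHz: a cryoprobe high-field system is far more
sensitive than a benchtop magnet, and because high-field lines are
~13× narrower (taller per unit area), equal height-referenced SNR
would paradoxically make the high-field integrals *noisier*.

`method_agreement()` summarizes paired differences against a reference
method (by convention the high-field library fit) with mean, SD, SE, a
t-based 95% CI — the t rather than normal quantile because n is small —
MAE, and per-sample absolute percentage errors (per-sample, not
per-timepoint-mean, which the emulated analysis leaves unspecified).
`compare_groups()` wraps Welch's unequal-variance t (Satterthwaite df)
and one-way ANOVA with Tukey HSD at $\alpha = 0.05$.

## Problem sizes and replication

The property battery (`replicate_cohort_properties()`) runs 50 seeded
cohorts of 36 spectra (32,768 points each) end to end — synthesis,
normalization, binning, OPLS-DA on days 2–5, GL and region
quantification of all samples against shared calibrations — in a few
minutes on one core, which is the scale at which the package's
stochastic claims (complete day-3–5 score separation, S-line sign
pattern, GL recovery error under 5% and below region integration,
final-day Welch significance) are stated and tested. Cached
unit-concentration basis spectra make per-cohort cost roughly
independent of panel size.

## Known limitations

- First-order rendering is the cohort default; strong-coupling
  distortion of the 0.9–1.1 ppm region at 60 MHz is available but not
  exercised by the default generator.
- No chemical-shift jitter, no unassigned fecal background, no
  within-subject correlation: synthetic results bound what the
  pipeline's arithmetic can do, not what real fecal spectra will allow.
- With 3 subjects per group, a twofold acetate shift and 20%
  biological CV, the day-5 Welch comparison has modest power; runs of
  the replication battery land near — sometimes below — a 90%
  significant fraction. That is a property of the emulated design
  (n = 3), not of the test implementation.
- Vendor raw formats (Bruker, Magritek directories) are unsupported;
  frequency-domain JCAMP-DX and two-column CSV are the exchange
  formats.
- OPLS-DA is strictly two-class; multi-class extensions and
  vendor-software file compatibility are out of scope.
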