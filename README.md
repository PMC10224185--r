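# benchnmr

Benchtop (60 MHz) versus high-field (800 MHz) ¹H NMR metabolomics,
end to end, with simulated ground truth.

Low-field benchtop NMR spectrometers are cheap, cryogen-free and
portable, which makes them attractive for point-of-care metabolomics —
but scalar couplings are fixed in Hz while the ppm axis stretches with
spectrometer frequency, so an *n*-line multiplet with coupling *J*
occupies

```
w = n · J / ν₀   ppm        (ν₀ = spectrometer frequency in MHz)
```

— about 13× more of the spectrum at 60 MHz than at 800 MHz. The
propionate CH₃ triplet (J = 7.70 Hz) spans 0.385 ppm at 60 MHz versus
0.029 ppm at 800 MHz, and signal overlap (not sensitivity) becomes the
limiting factor for identifying and quantifying metabolites in complex
samples such as fecal extracts.

`benchnmr` is for researchers evaluating what low-field instruments can
and cannot deliver for metabolomics. It provides:

- **Spin simulation** — first-order multiplets and exact
  full-Hamiltonian (strong-coupling) spectra for defined spin systems at
  any field, with a shipped library of the metabolites assignable in
  60 MHz fecal spectra plus the internal standards TSP and formate.
- **Cohort synthesis** — a study-shaped generator (2 groups × 3
  subjects × days 0–5, both fields) with colitis-direction fold
  changes, lognormal biological variation and known ground-truth
  concentrations.
- **Processing** — exponential apodization + FT, automated/manual
  phasing, iteratively reweighted polynomial baseline, TSP referencing
  and TSP-area normalization; JCAMP-DX and CSV I/O.
- **Chemometrics** — 0.04 ppm binning with water-region exclusion,
  Pareto/UV scaling, NIPALS PCA, two-class OPLS-DA with cross-validated
  Q², VIP and S-line diagnostics.
- **Quantification** — acetate by region integration,
  generalized-Lorentzian (pseudo-Voigt) curve fitting and template
  library fitting, calibrated on simulated 2–20 mM standards, with
  paired method-agreement statistics (mean difference, 95% CI, MAE,
  absolute percentage errors) and Welch/ANOVA group comparisons.

## Worked example

```r
library(benchnmr)

multiplet_envelope_ppm(7.70, 3, 60)    # 0.385 ppm at 60 MHz
multiplet_envelope_ppm(7.70, 3, 800)   # 0.029 ppm at 800 MHz

# simulate one full 60 MHz cohort, process, bin, discriminate
ch   <- synthesize_cohort(cohort_design(), fields = 60, seed = 1)
proc <- lapply(ch$spectra[["60"]], reference_and_normalize)
bm   <- assemble_bin_matrix(lapply(proc, bin_spectrum), ch$labels)
sub  <- bm$labels$day %in% 2:5
om   <- fit_oplsda(scale_columns(bm$values[sub, ], "pareto"),
                   bm$labels$group[sub], positive_class = "DSS")
om
#> <opls_model> 1 predictive + 1 orthogonal; R2X 0.697, R2Y 0.863, Q2 0.792

head(s_line(om, bm$centers)[order(-abs(om$s_covariance)), ], 5)
#>        ppm covariance correlation
#> 1.940 1.94      1.769       0.826   # acetate up in DSS
#> 1.900 1.90      1.645       0.747
#> 0.900 0.90     -0.960      -0.929   # butyrate/BCAA region down
#> 1.020 1.02     -0.793      -0.948
#> 2.380 2.38      0.710       0.862   # succinate up

# quantify acetate by GL curve fitting against a calibration curve
cal <- acetate_calibration(60, "gl", seed = 1)
cal
#> <calibration_model> response = -0.1377 + 0.7784 x mM, r2 = 0.99931 (2-20 mM)
est   <- quantify_acetate(proc, "gl", cal)
truth <- ch$truth[ch$truth$metabolite == "acetate", "true_concentration_mM"]
cor(est, truth)                       # 0.999
mean(abs(est - truth) / truth)        # 0.028 (2.8% mean abs. % error)

# does treated day-5 acetate exceed control?
d5 <- ch$labels$day == 5
compare_groups(est[d5], ch$labels$group[d5], "welch",
               alternative = "greater", positive_class = "DSS")
#> t = 3.31, df = 2.40, p = 0.031
```

The OPLS-DA scores separate the treated group completely from control
for days 3–5; the S-line says which spectral regions drive it (acetate
and succinate bins positive, butyrate/branched-chain amino-acid bins
negative); the GL fit recovers the generator's true acetate
concentrations to within a few percent even where neighbouring
multiplets overlap the window — while plain region integration misses
by ~15–20% at 60 MHz. `run_pipeline(run_config(seed = 1))` executes
the whole chain at both fields and writes every table, model summary
and figure into a run directory.

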