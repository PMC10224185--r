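Package: benchnmr
Title: Benchtop NMR Metabolomics: Spin Simulation, Chemometrics and
    Internal-Standard Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates 1D proton NMR spectra of defined spin systems at
    arbitrary spectrometer frequency (first-order and full-Hamiltonian
    modes), synthesizes study-shaped cohorts of fecal-extract spectra with
    known ground-truth concentrations, and carries them through a complete
    metabolomics pipeline: exponential apodization and Fourier transform,
    phase and baseline correction, TSP referencing and normalization,
    fixed-width spectral binning with solvent-region exclusion, Pareto and
    unit-variance scaling, NIPALS principal component analysis, two-class
    OPLS-DA with cross-validated Q2, VIP and S-line diagnostics, and
    acetate quantification by region integration, generalized-Lorentzian
    curve fitting and template library fitting, with calibration curves
    and paired method-agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
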