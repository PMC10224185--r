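# Region integration, generalized-Lorentzian fitting, template library
# fitting, calibration curves, agreement statistics and group tests.

# Acetate + TSP spectrum at 800 MHz (narrow lines, negligible overlap),
# TSP-normalized; intensities are per-mM proton-weighted areas.
acetate_tsp_spectrum <- function(acetate_mM, field = 800, noise_sd = 0,
                                 seed = NULL) {
  lib <- read_metabolite_library()
  axis <- default_grid(field, n = 32768)
  shape <- default_lineshape(field, noise_sd = noise_sd, seed = seed)
  shape0 <- shape; shape0$noise_sd <- 0
  y <- acetate_mM * render_spectrum(first_order_peaks(lib$acetate, field),
                                    axis, shape0)$intensity +
       0.5 * render_spectrum(first_order_peaks(lib$TSP, field),
                             axis, shape0)$intensity
  if (noise_sd > 0)
    y <- y + with(list(), {set.seed(seed); rnorm(length(axis), 0, noise_sd)})
  reference_and_normalize(nmr_spectrum(axis, y, field))
}

test_that("region integrals follow proton stoichiometry and linearity", {
  sp <- acetate_tsp_spectrum(10)
  # acetate area / TSP area = 3 * 10 / (9 * 0.5) after normalization
  expect_equal(integrate_region(sp, 1.8, 2.04), 3 * 10 / (9 * 0.5),
               tolerance = 0.02)
  # doubling the concentration doubles the integral
  sp2 <- acetate_tsp_spectrum(20)
  expect_equal(integrate_region(sp2, 1.8, 2.04) /
                 integrate_region(sp, 1.8, 2.04), 2, tolerance = 1e-3)
  # empty region is essentially zero
  expect_lt(abs(integrate_region(sp, 6.0, 6.5)),
            1e-3 * integrate_region(sp, 1.8, 2.04))
  expect_error(integrate_region(sp, 2.04, 1.8), "lo < hi")
  expect_error(integrate_region(sp, 11, 12), "outside")
})

test_that("GL self-fit recovers a pure pseudo-Voigt area to 0.1%", {
  axis <- default_grid(60, n = 16384)
  for (eta in c(0, 0.3)) {
    sp <- render_spectrum(peak_list(1.92, 5, 60), axis,
                          lineshape_params(1.4, eta))
    pk <- fit_gl_peak(sp, c(1.7, 2.1), n_nuisance = 0)
    expect_equal(pk$area, 5, tolerance = 1e-3)
    expect_equal(pk$center_ppm, 1.92, tolerance = 1e-5)
    expect_equal(pk$fwhm_hz, 1.4, tolerance = 1e-2)
  }
})

test_that("free mixing fits a Gaussian line better than pinned Lorentzian", {
  axis <- default_grid(60, n = 8192)
  sp <- render_spectrum(peak_list(1.92, 5, 60), axis,
                        lineshape_params(1.4, 1))  # pure Gaussian
  free <- fit_gl_peak(sp, c(1.7, 2.1), n_nuisance = 0)
  pinned <- fit_gl_peak(sp, c(1.7, 2.1), n_nuisance = 0, fix_eta = 0)
  expect_lt(attr(free, "residual_norm"), attr(pinned, "residual_norm"))
  expect_gt(free$eta, 0.9)
})

test_that("GL fitting beats region integration under multiplet overlap", {
  # acetate singlet with the glutamate multiplet leaking into its window
  lib <- read_metabolite_library()
  axis <- default_grid(60)
  shape <- lineshape_params(1.4, 0.1)
  conc <- 8
  y <- conc * render_spectrum(first_order_peaks(lib$acetate, 60), axis,
                              shape)$intensity +
       2 * render_spectrum(first_order_peaks(lib$glutamate, 60), axis,
                           shape)$intensity +
       0.5 * render_spectrum(first_order_peaks(lib$TSP, 60), axis,
                             shape)$intensity
  sp <- reference_and_normalize(nmr_spectrum(axis, y, 60))
  cal_gl <- acetate_calibration(60, "gl", seed = 3)
  cal_rg <- acetate_calibration(60, "region", seed = 3)
  est_gl <- calibrate_concentration(cal_gl,
                                    acetate_response(sp, "gl"))
  est_rg <- calibrate_concentration(cal_rg,
                                    acetate_response(sp, "region"))
  expect_lt(abs(est_gl - conc), abs(est_rg - conc))
  expect_lt(abs(est_gl - conc) / conc, 0.10)
})

test_that("library fitting recovers template amplitudes", {
  lib <- read_metabolite_library()
  axis <- default_grid(60, n = 16384)
  shape <- lineshape_params(1.4, 0.1)
  tpl <- render_templates(lib, c("acetate", "succinate"), 60, axis, shape)

  # self-fit of a single template
  sp1 <- nmr_spectrum(axis, 7 * Re(tpl$acetate$intensity), 60)
  c1 <- library_fit(sp1, tpl["acetate"], window = c(1.6, 2.2))
  expect_equal(unname(c1[["acetate"]]), 7, tolerance = 1e-6)

  # two-component mixture at finite signal-to-noise
  set.seed(8)
  ymix <- 5 * Re(tpl$acetate$intensity) + 3 * Re(tpl$succinate$intensity)
  ymix <- ymix + rnorm(length(axis), 0, max(ymix) / 100)
  cmix <- library_fit(nmr_spectrum(axis, ymix, 60), tpl,
                      window = c(1.6, 2.7))
  expect_equal(unname(cmix[["acetate"]]), 5, tolerance = 0.05)
  expect_equal(unname(cmix[["succinate"]]), 3, tolerance = 0.05)

  # absent template stays near zero
  c0 <- library_fit(sp1, tpl, window = c(1.6, 2.7))
  expect_lt(c0[["succinate"]], 0.02 * c0[["acetate"]])

  # collinear templates trigger a conditioning warning
  expect_warning(library_fit(sp1, list(a = tpl$acetate, b = tpl$acetate),
                             window = c(1.6, 2.2)), "condition")
})

test_that("calibration curves enforce their contracts", {
  cal <- suppressWarnings(build_calibration(c(2, 5, 10), c(4, 10, 20)))
  expect_equal(cal$slope, 2)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(calibrate_concentration(cal, 12), 6)
  expect_error(build_calibration(c(2, 2, 2), c(1, 2, 3)), "3 distinct")
  expect_error(build_calibration(c(2, 5, 10), c(3, 3, 3)), "degenerate")
})

test_that("agreement statistics match hand-computed values", {
  expect_error(method_agreement(1:3, 1:4), "paired")
  expect_error(method_agreement(1, 1), "n < 2")

  same <- method_agreement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mae, 0)
  expect_equal(c(same$ci95_lo, same$ci95_hi), c(0, 0))

  off <- method_agreement(c(1.5, 2.5, 3.5), c(1, 2, 3))
  expect_equal(off$mean, 0.5)
  expect_equal(off$sd, 0)
  expect_equal(off$mae, 0.5)

  # diffs 0.1, -0.3, 0.2: MAE 0.2, mean 0, CI half-width
  # t(0.975, 2) * sd/sqrt(3) = 4.302653 * 0.2645751/1.732051 = 0.657241
  ag <- method_agreement(c(1.1, 1.7, 2.2), c(1, 2, 2))
  expect_equal(ag$mae, 0.2, tolerance = 1e-9)
  expect_equal(ag$mean, 0, tolerance = 1e-9)
  expect_equal(ag$ci95_lo, -0.657241, tolerance = 1e-6)
  expect_equal(ag$ci95_hi, 0.657241, tolerance = 1e-6)
  expect_equal(ag$absolute_percentage_errors, c(10, 15, 10),
               tolerance = 1e-9)
})

test_that("group comparisons use Welch df and Tukey intervals correctly", {
  x <- c(5.1, 6.2, 5.8, 6.0)
  y <- c(7.9, 9.5, 8.8, 10.2, 9.1)
  res <- compare_groups(c(x, y), rep(c("a", "b"), c(4, 5)), "welch")
  # independent Satterthwaite oracle
  vx <- var(x) / 4; vy <- var(y) / 5
  df_oracle <- (vx + vy)^2 / (vx^2 / 3 + vy^2 / 4)
  expect_equal(unname(res$parameter), df_oracle, tolerance = 1e-6)
  expect_lt(res$p.value, 0.01)

  # identical groups: t = 0, p = 1
  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                         "welch")
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  # equal-mean groups at large n: Tukey intervals all cover zero
  set.seed(14)
  vals <- rnorm(300)
  grp <- rep(c("g1", "g2", "g3"), each = 100)
  tk <- compare_groups(vals, grp, "anova")$tukey$group
  expect_true(all(tk[, "lwr"] < 0 & tk[, "upr"] > 0))

  expect_error(compare_groups(1:4, c("a", "a", "a", "b")), "2 observations")
})

test_that("all three strategies are linear in true concentration", {
  lib <- read_metabolite_library()
  axis <- default_grid(60, n = 16384)
  shape <- lineshape_params(1.4, 0.1)
  make_sp <- function(cmM) {
    y <- cmM * render_spectrum(first_order_peaks(lib$acetate, 60), axis,
                               shape)$intensity +
         0.5 * render_spectrum(first_order_peaks(lib$TSP, 60), axis,
                               shape)$intensity
    reference_and_normalize(nmr_spectrum(axis, y, 60))
  }
  # templates on the TSP-referenced axis the spectra end up on
  tpl <- render_templates(lib, "acetate", 60, make_sp(4)$ppm,
                          lineshape_params(1.4, 0.1))
  resp <- vapply(c(4, 8), function(cmM) {
    sp <- make_sp(cmM)
    c(region = acetate_response(sp, "region"),
      gl = acetate_response(sp, "gl", n_nuisance = 0),
      lib = acetate_response(sp, "library", templates = tpl))
  }, numeric(3))
  expect_equal(unname(resp[, 2] / resp[, 1]), rep(2, 3), tolerance = 1e-3)
})
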