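# Processing chain: apodization + FT, phasing, baseline, TSP
# referencing and normalization.

make_two_peak <- function(n = 8192, eta = 0.1) {
  pk <- peak_list(c(2, 8), c(1, 2), 60)
  render_spectrum(pk, default_grid(60, n = n), lineshape_params(1.4, eta))
}

measured_fwhm_hz <- function(sp) {
  y <- Re(sp$intensity)
  i <- which.max(y)
  h <- y[i] / 2
  xl <- approx(y[1:i], sp$ppm[1:i], xout = h)$y
  xr <- approx(y[i:length(y)], sp$ppm[i:length(y)], xout = h)$y
  (xr - xl) * sp$field_MHz
}

test_that("transform inverts the synthetic FID exactly at lb = 0", {
  sp <- make_two_peak()
  fid <- spectrum_to_fid(sp)
  sp2 <- apodize_and_transform(fid, processing_config(lb_hz = 0))
  expect_equal(max(abs(Re(sp2$intensity) - Re(sp$intensity))) /
                 max(Re(sp$intensity)), 0, tolerance = 1e-6)
  expect_equal(sp2$ppm, sp$ppm, tolerance = 1e-9)
})

test_that("exponential apodization adds lb to the Lorentzian FWHM", {
  n <- 16384; dt <- 1e-3; T2 <- 0.5
  t <- (0:(n - 1)) * dt
  fid <- nmr_fid(exp(2i * pi * 100 * t - t / T2), dt, 60)
  natural <- 1 / (pi * T2)
  s0 <- apodize_and_transform(fid, processing_config(lb_hz = 0))
  s1 <- apodize_and_transform(fid, processing_config(lb_hz = 0.2))
  s5 <- apodize_and_transform(fid, processing_config(lb_hz = 5))
  expect_equal(measured_fwhm_hz(s0), natural, tolerance = 0.02)
  expect_equal(measured_fwhm_hz(s1), natural + 0.2, tolerance = 0.02)
  # strong broadening: width is lb-dominated
  expect_equal(measured_fwhm_hz(s5), natural + 5, tolerance = 0.05)
  expect_error(apodize_and_transform(list(), processing_config()), "nmr_fid")
  expect_error(nmr_fid(complex(0), 1e-3, 60), "length")
})

test_that("automated phasing recovers known rotations", {
  sp <- make_two_peak()
  s0 <- apodize_and_transform(spectrum_to_fid(sp),
                              processing_config(lb_hz = 0))

  # already phased: fitted angles stay near zero
  rec0 <- phase_correct(s0, processing_config())
  expect_lt(abs(rec0$meta$phase[["phi0"]]), 1)

  # known zero-order rotation comes back within a degree
  rot <- s0; rot$intensity <- rot$intensity * exp(1i * 30 * pi / 180)
  rec <- phase_correct(rot, processing_config())
  expect_equal(rec$meta$phase[["phi0"]], -30, tolerance = 1)

  # first-order ramp: negative residual below 1% of the maximum
  frac <- (s0$ppm - mean(range(s0$ppm))) / diff(range(s0$ppm))
  ramp <- s0; ramp$intensity <- ramp$intensity * exp(1i * (10 + 40 * frac) * pi / 180)
  rec1 <- phase_correct(ramp, processing_config())
  expect_lt(max(-Re(rec1$intensity), 0) / max(Re(rec1$intensity)), 0.01)

  # manual mode applies the given angles verbatim
  man <- phase_correct(rot, processing_config(phase_mode = "manual",
                                              phi0 = -30))
  expect_equal(man$intensity, Re(s0$intensity), tolerance = 1e-9)
  expect_error(phase_correct(make_two_peak(), processing_config()), "complex")
})

test_that("baseline correction removes drift but preserves peak area", {
  sp <- make_two_peak()
  y <- Re(sp$intensity)

  # flat offset subtracted essentially exactly
  off <- nmr_spectrum(sp$ppm, y + 2, 60)
  bc0 <- baseline_correct(off, degree = 0)
  quiet <- sp$ppm > 4 & sp$ppm < 6
  expect_lt(abs(median(bc0$intensity[quiet])), 1e-3)  # vs offset 2

  # linear tilt plus peaks: peak integral unchanged within 2%
  tilt <- nmr_spectrum(sp$ppm, y + 1 + 0.5 * sp$ppm, 60)
  bc1 <- baseline_correct(tilt, degree = 1)
  expect_equal(integrate_region(bc1, 1.5, 2.5),
               integrate_region(sp, 1.5, 2.5), tolerance = 0.02)

  # nothing to correct: spectrum unchanged within a tight bound
  bc2 <- baseline_correct(nmr_spectrum(sp$ppm, y, 60), degree = 3)
  expect_lt(max(abs(bc2$intensity - y)), 0.02 * max(y))

  expect_error(baseline_correct(sp, degree = -1), "degree")
})

test_that("TSP referencing shifts the axis and normalization is idempotent", {
  lib <- read_metabolite_library()
  axis <- default_grid(60)
  shape <- lineshape_params(1.4, 0.1)
  tsp <- first_order_peaks(lib$TSP, 60)
  ac <- first_order_peaks(lib$acetate, 60)
  y <- 0.5 * render_spectrum(peak_list(tsp$frequency_ppm + 0.02,
                                       tsp$intensity, 60),
                             axis, shape)$intensity +
       4 * render_spectrum(ac, axis, shape)$intensity
  sp <- nmr_spectrum(axis, y, 60)

  nn <- reference_and_normalize(sp)
  expect_equal(nn$meta$reference_shift_ppm, 0.02, tolerance = 1e-3)
  hw <- processing_config()$tsp_integration_halfwidth_ppm
  expect_equal(integrate_region(nn, -hw, hw), 1, tolerance = 1e-9)
  expect_true(nn$meta$normalized)

  # idempotence
  nn2 <- reference_and_normalize(nn)
  expect_equal(nn2$intensity, nn$intensity, tolerance = 1e-9)

  # global scale invariance
  sp7 <- nmr_spectrum(axis, 7 * y, 60)
  nn7 <- reference_and_normalize(sp7)
  expect_equal(nn7$intensity, nn$intensity, tolerance = 1e-9)

  # no TSP above noise: referencing error
  noise <- nmr_spectrum(axis, with(list(), {set.seed(1); rnorm(length(axis), 0, 1)}),
                        60)
  expect_error(reference_and_normalize(noise), "5x noise")
})

test_that("apodization preserves the acetate/TSP area ratio", {
  # causal FID of two Lorentzian singlets (TSP 0 ppm, acetate 1.92 ppm)
  n <- 32768; dt <- 1 / (11 * 60)  # sw 11 ppm at 60 MHz
  t <- (0:(n - 1)) * dt
  w <- 1.4  # natural FWHM in Hz
  line <- function(ppm, a) a * exp(2i * pi * (ppm - 5) * 60 * t - pi * w * t)
  fid <- nmr_fid(line(0, 4.5) + line(1.92, 12), dt, 60, carrier_ppm = 5)
  ratio <- function(s) {
    integrate_region(s, 1.6, 2.3) / integrate_region(s, -0.3, 0.3)
  }
  plain <- apodize_and_transform(fid, processing_config(lb_hz = 0))
  broadened <- apodize_and_transform(fid, processing_config(lb_hz = 2))
  expect_equal(ratio(broadened), ratio(plain), tolerance = 0.01)
})
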