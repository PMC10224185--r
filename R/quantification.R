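# Acetate quantification triad: region integration, generalized-
# Lorentzian (pseudo-Voigt) curve fitting, and template library fitting,
# plus calibration curves and paired method-agreement statistics.

#' Integrate a chemical-shift region
#'
#' Trapezoidal integral of the (TSP-normalized) intensity over
#' `[ppm_lo, ppm_hi]`. The simplest quantification strategy: fast, but
#' every neighbouring multiplet that leaks into the region is counted,
#' which at 60 MHz is the dominant error source.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param ppm_lo,ppm_hi Region bounds in ppm (`lo < hi`, inside the axis).
#' @return The integral (TSP-normalized units if the spectrum is
#'   normalized).
#' @export
integrate_region <- function(spectrum, ppm_lo, ppm_hi) {
  region_integral(spectrum$ppm, Re(spectrum$intensity), ppm_lo, ppm_hi)
}

#' Generalized-Lorentzian peak description
#'
#' The flexible single-peak lineshape used for deconvolution: here an
#' area-parameterized pseudo-Voigt, `eta * Gaussian + (1 - eta) *
#' Lorentzian`, interpolating Lorentzian and Gaussian character with a
#' free mixing parameter.
#'
#' @param center_ppm Peak position in ppm.
#' @param fwhm_hz Full width at half maximum in Hz.
#' @param eta Gaussian fraction in `[0, 1]`.
#' @param area Analytic peak area.
#' @return A `gl_peak` list.
#' @export
gl_peak <- function(center_ppm, fwhm_hz, eta = 0.1, area = 1) {
  if (fwhm_hz <= 0) stop_invalid("fwhm must be > 0")
  if (eta < 0 || eta > 1) stop_invalid("eta must lie in [0, 1]")
  structure(list(center_ppm = center_ppm, fwhm_hz = fwhm_hz, eta = eta,
                 area = area), class = "gl_peak")
}

#' Fit a generalized-Lorentzian peak in a window
#'
#' Nonlinear least squares of one target pseudo-Voigt peak, up to
#' `n_nuisance` additional pseudo-Voigt peaks absorbing overlapping
#' neighbours, and a linear local baseline, over the given window.
#' Nuisance peaks are seeded at the largest residual maxima after an
#' initial target-only fit. Returns the fitted target peak with its
#' analytic area (TSP-normalized if the spectrum is), so tail area lost
#' outside the window is recovered analytically -- the central advantage
#' over region integration.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window `c(lo, hi)` ppm window containing the target peak.
#' @param init Optional `gl_peak` initial guess for the target (default:
#'   tallest point in the window, field-default width).
#' @param n_nuisance Maximum number of nuisance peaks (default 2).
#' @param max_iter Maximum Levenberg-Marquardt iterations (default 500).
#' @param ftol Relative residual-change convergence tolerance
#'   (default 1e-10).
#' @param fix_eta If non-`NULL`, pin the mixing parameter of every
#'   component to this value instead of fitting it.
#' @return A `gl_peak` for the target, with attributes `residual_norm`,
#'   `nuisance` (list of fitted nuisance peaks) and `baseline`.
#' @export
fit_gl_peak <- function(spectrum, window, init = NULL, n_nuisance = 2,
                        max_iter = 500, ftol = 1e-10, fix_eta = NULL) {
  x <- spectrum$ppm
  sel <- x >= window[1] & x <= window[2]
  if (sum(sel) < 10) stop_invalid("window contains too few points")
  xs <- x[sel]
  ys <- Re(spectrum$intensity)[sel]
  field <- spectrum$field_MHz
  if (is.null(init)) {
    init <- gl_peak(xs[which.max(ys)],
                    fwhm_hz = if (field < 200) 1.4 else 1.0,
                    eta = 0.1,
                    area = max(ys) * pi * (if (field < 200) 1.4 else 1.0) /
                      field / 2)
  }

  fit_model <- function(centers, fwhms, etas, areas) {
    k <- length(centers)
    if (!is.null(fix_eta)) etas <- rep(fix_eta, k)
    eta_lo <- if (is.null(fix_eta)) 0 else fix_eta
    eta_hi <- if (is.null(fix_eta)) 1 else fix_eta
    par <- c(rbind(centers, fwhms, etas, areas), 0, 0)
    lower <- c(rbind(rep(window[1], k), rep(1e-3, k), rep(eta_lo, k),
                     rep(0, k)), -Inf, -Inf)
    upper <- c(rbind(rep(window[2], k), rep(50, k), rep(eta_hi, k),
                     rep(Inf, k)), Inf, Inf)
    model <- function(p) {
      y <- p[4 * k + 1] + p[4 * k + 2] * (xs - mean(xs))
      for (j in seq_len(k)) {
        pj <- p[(4 * (j - 1) + 1):(4 * j)]
        y <- y + pj[4] * pseudo_voigt(xs, pj[1], pj[2] / field, pj[3])
      }
      y
    }
    res <- minpack.lm::nls.lm(par, lower, upper,
                              fn = function(p) ys - model(p),
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, ftol = ftol, ptol = 1e-12))
    list(par = res$par, k = k, model = model,
         rnorm = sqrt(sum(res$fvec^2)), info = res$info)
  }

  f1 <- fit_model(init$center_ppm, init$fwhm_hz, init$eta, init$area)
  best <- f1
  if (n_nuisance > 0) {
    resid <- ys - f1$model(f1$par)
    cs <- f1$par[1]; fw <- f1$par[2]; et <- f1$par[3]; ar <- f1$par[4]
    for (j in seq_len(n_nuisance)) {
      i <- which.max(resid)
      if (resid[i] < 0.02 * max(ys)) break
      cs <- c(cs, xs[i]); fw <- c(fw, fw[1]); et <- c(et, et[1])
      ar <- c(ar, max(resid[i], 0) * pi * fw[1] / field / 2)
      fnew <- fit_model(cs, fw, et, ar)
      if (fnew$rnorm < best$rnorm) best <- fnew
      resid <- ys - fnew$model(fnew$par)
    }
  }
  if (best$info == 0)
    stop("GL fit did not converge; residual norm ", format(best$rnorm))
  p <- best$par
  # target = fitted component closest to the initial target center
  centers <- p[4 * (seq_len(best$k) - 1) + 1]
  tgt <- which.min(abs(centers - init$center_ppm))
  if (centers[tgt] <= window[1] + 1e-9 || centers[tgt] >= window[2] - 1e-9)
    stop("fitted target center migrated to the window boundary")
  pj <- p[(4 * (tgt - 1) + 1):(4 * tgt)]
  out <- gl_peak(pj[1], pj[2], pj[3], pj[4])
  attr(out, "residual_norm") <- best$rnorm
  attr(out, "nuisance") <- lapply(setdiff(seq_len(best$k), tgt), function(j) {
    q <- p[(4 * (j - 1) + 1):(4 * j)]
    gl_peak(q[1], q[2], q[3], q[4])
  })
  attr(out, "baseline") <- p[4 * best$k + 1:2]
  out
}

#' Calibrate a lineshape on the TSP signal
#'
#' Fits a single generalized-Lorentzian to the TSP singlet and returns
#' the fitted width and mixing as a [lineshape_params()], for
#' pre-defining the peak shape of library templates.
#'
#' @param spectrum An `nmr_spectrum` containing TSP near 0 ppm.
#' @param halfwidth_ppm TSP fit window half-width (default 0.1).
#' @return A `lineshape_params`.
#' @export
calibrate_lineshape_from_tsp <- function(spectrum, halfwidth_ppm = 0.1) {
  pk <- fit_gl_peak(spectrum, c(-halfwidth_ppm, halfwidth_ppm), n_nuisance = 0)
  lineshape_params(width_hz = pk$fwhm_hz, eta = pk$eta)
}

#' Render library templates for curve fitting
#'
#' Renders each requested metabolite's multiplet pattern at 1 mM
#' equivalent (intensity = proton count) on the given axis with a fixed
#' lineshape, typically pre-calibrated on the TSP signal of the spectrum
#' being fitted.
#'
#' @param library Metabolite library ([read_metabolite_library()]).
#' @param metabolites Character vector of template names.
#' @param field_MHz Spectrometer frequency.
#' @param axis Ppm axis of the spectrum to be fitted.
#' @param shape A [lineshape_params()] (noiseless).
#' @param mode `"first_order"` or `"hamiltonian"`.
#' @return Named list of template `nmr_spectrum` objects (per-mM response).
#' @export
render_templates <- function(library, metabolites, field_MHz, axis, shape,
                             mode = "first_order") {
  shape$noise_sd <- 0; shape$baseline_coeffs <- 0
  out <- lapply(metabolites, function(m) {
    sys <- library[[m]]
    if (is.null(sys)) stop_invalid("metabolite not in library: ", m)
    pk <- if (mode == "hamiltonian" && sum(sys$n_protons) <= 8)
      full_hamiltonian_peaks(sys, field_MHz) else first_order_peaks(sys, field_MHz)
    suppressWarnings(render_spectrum(pk, axis, shape))
  })
  names(out) <- metabolites
  out
}

#' Template library fitting
#'
#' Non-negative least squares of template amplitudes to the spectrum over
#' a fit window, with an unconstrained linear local baseline. Template
#' responses are per-mM, so fitted amplitudes are concentration estimates
#' in mM up to the spectrum's normalization scale; the residual
#' ("subtraction line") is returned for inspection. A conditioning
#' warning with the design-matrix condition number is issued when
#' templates are nearly collinear over the window.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param templates Named list of template spectra from
#'   [render_templates()] on the same axis.
#' @param window `c(lo, hi)` ppm fit window.
#' @param targets Which template names to report (default all).
#' @return Named numeric vector of concentrations (mM-equivalent), with
#'   attributes `residual` (ppm/intensity data frame over the window) and
#'   `condition_number`.
#' @export
library_fit <- function(spectrum, templates, window = NULL, targets = NULL) {
  x <- spectrum$ppm
  sel <- if (is.null(window)) rep(TRUE, length(x)) else
    x >= window[1] & x <= window[2]
  xs <- x[sel]
  ys <- Re(spectrum$intensity)[sel]
  A <- vapply(templates, function(tp) {
    if (xs[1] < tp$ppm[1] - 1e-6 || xs[length(xs)] > tp$ppm[length(tp$ppm)] + 1e-6)
      stop_invalid("template axis does not cover the fit window")
    # templates are interpolated onto the spectrum axis; exact when the
    # axes coincide, and tolerant of the one-grid-step jitter TSP
    # referencing introduces between samples
    stats::approx(tp$ppm, Re(tp$intensity), xout = xs, rule = 2)$y
  }, numeric(sum(sel)))
  # a template is only estimable from a window that contains a real part
  # of its peak; tail-only templates (near-linear over the window, hence
  # collinear with the baseline) are excluded and reported as zero
  global_max <- vapply(templates, function(tp) max(abs(Re(tp$intensity))), 0)
  active <- apply(abs(A), 2, max) > 1e-3 * global_max
  kappa_val <- kappa(A[, active, drop = FALSE], exact = FALSE)
  if (kappa_val > 1e6)
    warning("near-collinear templates over the fit window; condition number ",
            format(kappa_val, digits = 3))
  # unconstrained baseline via +/- column pairs inside NNLS
  b1 <- rep(1, length(xs)); b2 <- (xs - mean(xs))
  Afull <- cbind(A[, active, drop = FALSE], b1, -b1, b2, -b2)
  fit <- pracma::lsqnonneg(Afull, ys)
  conc <- numeric(length(templates))
  conc[active] <- fit$x[seq_len(sum(active))]
  names(conc) <- names(templates)
  resid <- ys - as.numeric(Afull %*% fit$x)
  if (!is.null(targets)) conc <- conc[targets]
  attr(conc, "residual") <- data.frame(ppm = xs, intensity = resid)
  attr(conc, "condition_number") <- kappa_val
  conc
}

#' Build a calibration curve
#'
#' Ordinary least squares of method response on known concentration,
#' with intercept, over at least three distinct levels.
#'
#' @param levels_mM Known concentrations (mM).
#' @param responses Method responses (one per entry; replicates appear as
#'   repeated levels).
#' @return A `calibration_model` with `slope`, `intercept`, `r_squared`,
#'   `range_mM` and the underlying `lm` fit.
#' @export
build_calibration <- function(levels_mM, responses) {
  if (length(levels_mM) != length(responses))
    stop_invalid("levels and responses differ in length")
  if (length(unique(levels_mM)) < 3)
    stop_invalid("calibration needs >= 3 distinct levels")
  if (stats::sd(responses) == 0)
    stop_invalid("degenerate calibration: responses have zero variance")
  fit <- stats::lm(responses ~ levels_mM)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 range_mM = range(levels_mM), fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> response = %.4g + %.4g x mM, r2 = %.5f (%g-%g mM)\n",
              x$intercept, x$slope, x$r_squared, x$range_mM[1], x$range_mM[2]))
  invisible(x)
}

#' Invert a calibration curve
#' @param model A `calibration_model`.
#' @param response Observed responses.
#' @return Estimated concentrations in mM.
#' @export
calibrate_concentration <- function(model, response) {
  (response - model$intercept) / model$slope
}

#' Paired agreement statistics between two quantification methods
#'
#' Differences `estimate - reference` per paired sample, summarized by
#' mean, SD, SE, a t-based 95\% confidence interval (appropriate at the
#' small n of paired method comparisons), mean absolute error, and
#' per-pair absolute percentage errors relative to the reference.
#'
#' @param estimates Numeric vector of method estimates.
#' @param reference Paired reference estimates (same length/order).
#' @return An `agreement_stats` list.
#' @export
method_agreement <- function(estimates, reference) {
  if (length(estimates) != length(reference))
    stop_invalid("estimates and reference must be paired (equal length)")
  n <- length(estimates)
  if (n < 2) stop_invalid("confidence interval undefined for n < 2")
  d <- estimates - reference
  m <- mean(d); s <- stats::sd(d); se <- s / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  structure(list(n = n, differences = d, mean = m, sd = s, se = se,
                 ci95_lo = m - tq * se, ci95_hi = m + tq * se,
                 mae = mean(abs(d)),
                 absolute_percentage_errors = 100 * abs(d) / abs(reference)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d  mean diff %.3f (95%% CI %.3f..%.3f)  MAE %.3f  MAPE %.1f%%\n",
    x$n, x$mean, x$ci95_lo, x$ci95_hi, x$mae,
    mean(x$absolute_percentage_errors)))
  invisible(x)
}

#' Compare concentrations between groups
#'
#' Welch's unequal-variances t-test for two groups (with Satterthwaite
#' degrees of freedom), or one-way ANOVA with Tukey's honest significant
#' difference post-hoc intervals for two or more groups. Significance
#' level alpha = 0.05 by convention.
#'
#' @param values Numeric vector of concentrations.
#' @param group Group labels, same length.
#' @param test `"welch"` or `"anova"`.
#' @param alternative Sidedness for Welch (`"two.sided"` default); the
#'   difference tested is `positive_class` minus the other group, so
#'   `"greater"` asks whether the positive class exceeds the other.
#' @param positive_class Group whose mean enters the difference first
#'   (default: the first factor level).
#' @return For `"welch"`: the `htest` from [stats::t.test()]. For
#'   `"anova"`: list with the `aov` fit, F statistic, p value, and
#'   `TukeyHSD` intervals.
#' @export
compare_groups <- function(values, group, test = c("welch", "anova"),
                           alternative = "two.sided", positive_class = NULL) {
  test <- match.arg(test)
  group <- as.factor(group)
  if (any(table(group) < 2)) stop_invalid("each group needs >= 2 observations")
  if (test == "welch") {
    if (nlevels(group) != 2) stop_invalid("Welch's test needs exactly 2 groups")
    if (!is.null(positive_class)) group <- stats::relevel(group, positive_class)
    stats::t.test(values ~ group, var.equal = FALSE, alternative = alternative)
  } else {
    fit <- stats::aov(values ~ group)
    sm <- summary(fit)[[1]]
    list(fit = fit, F = sm$`F value`[1], p = sm$`Pr(>F)`[1],
         tukey = stats::TukeyHSD(fit))
  }
}
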