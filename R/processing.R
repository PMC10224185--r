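#' Processing configuration
#'
#' Parameters of the spectrum processing chain: exponential line
#' broadening before Fourier transformation, phase-correction mode,
#' baseline polynomial degree, and the windows used for TSP referencing
#' and normalization.
#'
#' @param lb_hz Exponential line broadening in Hz (default 0.2).
#' @param phase_mode `"automated"` (minimize squared negative intensity)
#'   or `"manual"` (use `phi0`/`phi1` as given).
#' @param phi0,phi1 Manual zero- and first-order phase in degrees.
#' @param baseline_degree Polynomial degree for baseline correction
#'   (default 3).
#' @param tsp_search_window_ppm Half-width of the window around 0 ppm
#'   searched for the TSP maximum (default 0.3).
#' @param tsp_integration_halfwidth_ppm Half-width of the TSP
#'   integration window (default 0.05); wide enough to cover the singlet
#'   plus low-field broadening.
#' @return A `processing_config` list.
#' @export
processing_config <- function(lb_hz = 0.2, phase_mode = c("automated", "manual"),
                              phi0 = 0, phi1 = 0, baseline_degree = 3,
                              tsp_search_window_ppm = 0.3,
                              tsp_integration_halfwidth_ppm = 0.05) {
  if (!is_number(lb_hz) || lb_hz < 0) stop_invalid("lb_hz must be >= 0")
  structure(list(lb_hz = lb_hz, phase_mode = match.arg(phase_mode),
                 phi0 = phi0, phi1 = phi1, baseline_degree = baseline_degree,
                 tsp_search_window_ppm = tsp_search_window_ppm,
                 tsp_integration_halfwidth_ppm = tsp_integration_halfwidth_ppm),
            class = "processing_config")
}

# Apply phase angles (degrees) to a complex spectrum; phi1 is a linear
# ramp across the axis, pivoted at its centre.
#' @keywords internal
#' @noRd
apply_phase <- function(spectrum, phi0, phi1) {
  ppm <- spectrum$ppm
  frac <- (ppm - mean(range(ppm))) / diff(range(ppm))
  ph <- (phi0 + phi1 * frac) * pi / 180
  out <- spectrum
  out$intensity <- spectrum$intensity * exp(1i * ph)
  out$meta$phase <- c(phi0 = phi0, phi1 = phi1)
  out
}

#' Phase-correct a spectrum
#'
#' Applies zero- and first-order phase correction. In automated mode the
#' angles are found by minimizing the sum of squared negative real
#' intensities (a pure-absorption spectrum has none); manual mode applies
#' the configured angles directly, mirroring interactive phasing.
#'
#' @param spectrum A complex-valued `nmr_spectrum`.
#' @param config A [processing_config()].
#' @return An `nmr_spectrum` with real (absorption-mode) intensities; the
#'   applied angles are stored in `meta$phase`.
#' @export
phase_correct <- function(spectrum, config = processing_config()) {
  if (!is.complex(spectrum$intensity)) {
    if (config$phase_mode == "automated")
      stop_invalid("automated phasing needs a complex spectrum")
    return(spectrum)
  }
  if (config$phase_mode == "manual") {
    out <- apply_phase(spectrum, config$phi0, config$phi1)
  } else {
    obj <- function(par) {
      re <- Re(apply_phase(spectrum, par[1], par[2])$intensity)
      sum(pmin(re, 0)^2) - 1e-6 * sum(re)  # tiny tie-break toward positive total
    }
    # coarse phi0 scan to avoid the sign-flipped local optimum
    coarse <- vapply(seq(-180, 170, by = 10),
                     function(p0) obj(c(p0, 0)), 0)
    p0 <- seq(-180, 170, by = 10)[which.min(coarse)]
    fit <- stats::optim(c(p0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    out <- apply_phase(spectrum, fit$par[1], fit$par[2])
  }
  out$intensity <- Re(out$intensity)
  out
}

#' Baseline-correct a spectrum
#'
#' Fits a low-order polynomial by iteratively reweighted least squares:
#' points rising above the running fit (signal) are progressively
#' down-weighted so the polynomial tracks signal-free regions, then the
#' fit is subtracted.
#'
#' @param spectrum A real-valued `nmr_spectrum`.
#' @param degree Polynomial degree (default from `config`).
#' @param n_iter Reweighting iterations (default 15).
#' @return Corrected `nmr_spectrum`.
#' @export
baseline_correct <- function(spectrum, degree = 3, n_iter = 15) {
  if (!is_number(degree) || degree < 0) stop_invalid("degree must be >= 0")
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  xs <- (x - mean(x)) / stats::sd(x)
  X <- stats::poly(xs, degree = max(degree, 1), raw = TRUE)
  if (degree == 0) X <- X[, 0, drop = FALSE]
  X <- cbind(1, X)
  w <- rep(1, length(y))
  base <- rep(stats::median(y), length(y))
  for (it in seq_len(n_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    base <- as.numeric(X %*% fit$coefficients)
    r <- y - base
    sigma <- stats::mad(r[r <= 0], center = 0)
    if (!is.finite(sigma) || sigma == 0) sigma <- stats::mad(r) + 1e-12
    w <- ifelse(r > 2 * sigma, 1e-4, 1)
  }
  out <- spectrum
  out$intensity <- as.numeric(y - base)
  out$meta$baseline_degree <- degree
  out
}

#' Reference the chemical-shift axis to TSP and normalize to its area
#'
#' Locates the TSP maximum within the search window around 0 ppm, shifts
#' the axis so the maximum sits exactly at 0.000 ppm, then divides all
#' intensities by the TSP integral over the configured window so the TSP
#' area equals 1 by definition. Applying the operation twice equals
#' applying it once.
#'
#' @param spectrum A real-valued `nmr_spectrum` containing a TSP singlet.
#' @param config A [processing_config()].
#' @return A referenced, normalized `nmr_spectrum` with
#'   `meta$normalized = TRUE` and the divisor in `meta$tsp_area`.
#' @export
reference_and_normalize <- function(spectrum, config = processing_config()) {
  ppm <- spectrum$ppm
  y <- Re(spectrum$intensity)
  win <- abs(ppm) <= config$tsp_search_window_ppm
  if (!any(win)) stop_invalid("TSP search window outside the spectrum axis")
  noise <- stats::mad(diff(y[win])) / sqrt(2)
  imax <- which(win)[which.max(y[win])]
  if (y[imax] < 5 * noise && noise > 0)
    stop_invalid("no peak above 5x noise in the TSP search window; cannot reference")
  shift <- ppm[imax]
  ppm2 <- ppm - shift
  hw <- config$tsp_integration_halfwidth_ppm
  area <- region_integral(ppm2, y, -hw, hw)
  if (area <= 0) stop_invalid("non-positive TSP area; cannot normalize")
  out <- spectrum
  out$ppm <- ppm2
  out$intensity <- y / area
  out$meta$normalized <- TRUE
  out$meta$tsp_area <- area
  out$meta$reference_shift_ppm <- shift
  out
}
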