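#' Construct a spectrum object
#'
#' A frequency-domain 1D spectrum: strictly ascending ppm axis, matching
#' intensity vector (real or complex), spectrometer frequency, and a
#' metadata list tracking acquisition scheme and normalization state.
#' The axis is stored ascending; NMR display convention (ppm decreasing
#' to the right) is applied only at plot time.
#'
#' @param ppm Strictly monotone ppm axis.
#' @param intensity Intensity vector of equal length (real or complex).
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @param meta Named list of metadata; `normalized` defaults to `FALSE`.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, field_MHz, meta = list()) {
  if (length(ppm) != length(intensity))
    stop_invalid("ppm axis and intensity differ in length")
  d <- diff(ppm)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop_invalid("ppm axis must be strictly monotone")
  if (length(d) && d[1] < 0) {  # normalize to ascending
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  if (is.null(meta$normalized)) meta$normalized <- FALSE
  structure(list(ppm = as.numeric(ppm), intensity = intensity,
                 field_MHz = field_MHz, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f-%.3f ppm, %g MHz%s%s\n",
              length(x$ppm), min(x$ppm), max(x$ppm), x$field_MHz,
              if (is.complex(x$intensity)) ", complex" else "",
              if (isTRUE(x$meta$normalized)) ", TSP-normalized" else ""))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ..., xlab = "ppm", ylab = "intensity") {
  graphics::plot(x$ppm, Re(x$intensity), type = "l", xlim = rev(range(x$ppm)),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Lineshape and noise parameters for spectrum rendering
#'
#' @param width_hz Full width at half maximum of each line, in Hz.
#'   Benchtop magnets are less homogeneous than superconducting ones, so a
#'   wider default is appropriate at 60 MHz (see [default_lineshape()]).
#' @param eta Gaussian fraction of the pseudo-Voigt profile, in `[0, 1]`
#'   (0 = pure Lorentzian).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added in
#'   the frequency domain (0 = noiseless).
#' @param baseline_coeffs Polynomial baseline coefficients (intercept
#'   first), evaluated on the ppm axis.
#' @param seed RNG seed for the noise draw (`NULL` = use current RNG state).
#' @return A `lineshape_params` list.
#' @export
lineshape_params <- function(width_hz = 1.0, eta = 0.1, noise_sd = 0,
                             baseline_coeffs = 0, seed = NULL) {
  if (!is_number(width_hz) || width_hz <= 0) stop_invalid("width_hz must be > 0")
  if (!is_number(eta) || eta < 0 || eta > 1) stop_invalid("eta must lie in [0, 1]")
  structure(list(width_hz = width_hz, eta = eta, noise_sd = noise_sd,
                 baseline_coeffs = baseline_coeffs, seed = seed),
            class = "lineshape_params")
}

#' Default lineshape for a given spectrometer frequency
#'
#' 1.0 Hz FWHM at 800 MHz and 1.4 Hz at 60 MHz, pseudo-Voigt mixing 0.1.
#' Chosen to reproduce the qualitative congestion of published benchtop
#' versus high-field fecal spectra; neither instrument's true linewidth
#' is part of the simulated study design.
#'
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @inheritParams lineshape_params
#' @return A `lineshape_params` list.
#' @export
default_lineshape <- function(field_MHz, noise_sd = 0, seed = NULL) {
  lineshape_params(width_hz = if (field_MHz < 200) 1.4 else 1.0,
                   eta = 0.1, noise_sd = noise_sd, seed = seed)
}

# Area-normalized pseudo-Voigt profile on axis x (same units as fwhm).
#' @keywords internal
#' @noRd
pseudo_voigt <- function(x, center, fwhm, eta) {
  hw <- fwhm / 2
  lor <- (hw / pi) / ((x - center)^2 + hw^2)
  if (eta == 0) return(lor)
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  gau <- exp(-(x - center)^2 / (2 * sg^2)) / (sg * sqrt(2 * pi))
  eta * gau + (1 - eta) * lor
}

#' Default simulated ppm grid
#'
#' -0.5 to 10.5 ppm with 32768 points at low field and 65536 points at
#' high field, mirroring typical time-domain sizes of the two instrument
#' classes. The margin beyond the 0-10 ppm analysis window keeps the TSP
#' reference singlet at 0.0 ppm (and its integration window) fully on
#' the axis.
#'
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @param ppm_range Axis limits (default `c(-0.5, 10.5)`).
#' @param n Number of points (default by field).
#' @return Numeric ppm axis.
#' @export
default_grid <- function(field_MHz, ppm_range = c(-0.5, 10.5), n = NULL) {
  if (is.null(n)) n <- if (field_MHz < 200) 32768L else 65536L
  seq(ppm_range[1], ppm_range[2], length.out = n)
}

#' Render a stick spectrum onto a continuous axis
#'
#' Sums area-normalized pseudo-Voigt lines (one per peak-list entry,
#' scaled by its intensity), then adds an optional polynomial baseline
#' and seeded frequency-domain Gaussian noise. With zero noise, the
#' numeric integral over an isolated multiplet reproduces its stick
#' intensity to within the Lorentzian tail truncation of the axis
#' (under 1\% for axes extending a few hundred linewidths past the line).
#'
#' @param peaks A [peak_list()].
#' @param axis Ppm grid (default [default_grid()] for the peak list's field).
#' @param shape A [lineshape_params()] (default [default_lineshape()]).
#' @return An `nmr_spectrum`. If any line lies closer than 10 linewidths
#'   to the axis edge (or outside it), a truncation warning is issued and
#'   recorded in `meta$truncated`.
#' @export
render_spectrum <- function(peaks, axis = NULL, shape = NULL) {
  field <- peaks$field_MHz
  if (is.null(axis)) axis <- default_grid(field)
  if (is.null(shape)) shape <- default_lineshape(field)
  fwhm_ppm <- shape$width_hz / field
  truncated <- FALSE
  if (length(peaks$frequency_ppm)) {
    lo <- min(peaks$frequency_ppm) - 10 * fwhm_ppm
    hi <- max(peaks$frequency_ppm) + 10 * fwhm_ppm
    if (lo < axis[1] || hi > axis[length(axis)]) {
      truncated <- TRUE
      warning("axis does not cover all lines +/- 10 linewidths; ",
              "multiplet areas will be truncated")
    }
  }
  y <- numeric(length(axis))
  for (i in seq_along(peaks$frequency_ppm)) {
    y <- y + peaks$intensity[i] *
      pseudo_voigt(axis, peaks$frequency_ppm[i], fwhm_ppm, shape$eta)
  }
  bc <- shape$baseline_coeffs
  if (any(bc != 0)) {
    for (d in seq_along(bc)) y <- y + bc[d] * axis^(d - 1)
  }
  if (shape$noise_sd > 0) {
    y <- y + with_fixed_seed(shape$seed,
                             stats::rnorm(length(axis), 0, shape$noise_sd))
  }
  nmr_spectrum(axis, y, field,
               meta = list(normalized = FALSE, truncated = truncated,
                           lineshape = shape[c("width_hz", "eta", "noise_sd")]))
}
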