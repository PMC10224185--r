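#' Construct a free induction decay
#'
#' @param signal Complex time-domain vector.
#' @param dwell_s Dwell time (sampling interval) in seconds.
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @param carrier_ppm Ppm value of the carrier (zero-frequency) position;
#'   the transformed axis is centred here.
#' @param meta Optional metadata list (e.g. acquisition scheme label).
#' @return An object of class `nmr_fid`.
#' @export
nmr_fid <- function(signal, dwell_s, field_MHz, carrier_ppm = 5, meta = list()) {
  if (length(signal) == 0) stop_invalid("FID must have positive length")
  if (!is_number(dwell_s) || dwell_s <= 0) stop_invalid("dwell time must be > 0")
  structure(list(signal = as.complex(signal), dwell_s = dwell_s,
                 field_MHz = field_MHz, carrier_ppm = carrier_ppm, meta = meta),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d points, dwell %.3g s (sw %.0f Hz), %g MHz\n",
              length(x$signal), x$dwell_s, 1 / x$dwell_s, x$field_MHz))
  invisible(x)
}

#' Inverse-transform a spectrum to a synthetic FID
#'
#' Produces the time-domain signal whose discrete Fourier transform under
#' [apodize_and_transform()] (with zero line broadening) reproduces the
#' input spectrum on the same axis. Used to exercise the processing chain
#' on simulated data, which is rendered in the frequency domain.
#'
#' @param spectrum An `nmr_spectrum` on a uniform ppm grid.
#' @return An `nmr_fid`.
#' @export
spectrum_to_fid <- function(spectrum) {
  ppm <- spectrum$ppm
  n <- length(ppm)
  dppm <- diff(ppm)
  if (max(abs(dppm - dppm[1])) > 1e-9 * abs(dppm[1]))
    stop_invalid("spectrum axis must be uniform for the FID round-trip")
  sw_hz <- (ppm[n] - ppm[1]) / (n - 1) * n * spectrum$field_MHz
  dwell <- 1 / sw_hz
  carrier <- ppm[floor(n / 2) + 1]
  s <- as.complex(spectrum$intensity)
  fid <- stats::fft(ifftshift1(s), inverse = TRUE) / n
  nmr_fid(fid, dwell, spectrum$field_MHz, carrier_ppm = carrier,
          meta = spectrum$meta)
}

#' Apodize an FID and Fourier-transform it to a spectrum
#'
#' Multiplies the FID by the exponential window `exp(-pi * lb * t)` --
#' under this convention `lb` adds directly to the full width at half
#' maximum of every (Lorentzian) line, in Hz -- then applies the discrete
#' Fourier transform and converts the frequency axis to ppm about the
#' carrier.
#'
#' @param fid An `nmr_fid`.
#' @param config A [processing_config()]; `config$lb_hz` is the line
#'   broadening in Hz (default 0.2).
#' @return A complex-valued `nmr_spectrum`.
#' @export
apodize_and_transform <- function(fid, config = processing_config()) {
  if (!inherits(fid, "nmr_fid")) stop_invalid("fid must be an nmr_fid")
  n <- length(fid$signal)
  t <- (seq_len(n) - 1) * fid$dwell_s
  s <- fid$signal * exp(-pi * config$lb_hz * t)
  spec <- fftshift1(stats::fft(s))
  freq_hz <- (seq_len(n) - 1 - floor(n / 2)) / (n * fid$dwell_s)
  ppm <- fid$carrier_ppm + freq_hz / fid$field_MHz
  nmr_spectrum(ppm, spec, fid$field_MHz,
               meta = c(fid$meta[setdiff(names(fid$meta), "normalized")],
                        list(normalized = FALSE, lb_hz = config$lb_hz)))
}
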