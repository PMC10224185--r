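# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
stop_invalid <- function(...) {
  stop(structure(class = c("benchnmr_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Trapezoidal cumulative integral of y over x (x strictly increasing).
#' @keywords internal
#' @noRd
cumtrapz0 <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

# Trapezoidal integral of y over [lo, hi], with linear interpolation of the
# cumulative integral at the interval edges so bin edges need not coincide
# with grid points.
#' @keywords internal
#' @noRd
region_integral <- function(x, y, lo, hi) {
  if (lo >= hi) stop_invalid("integration region must have lo < hi")
  if (lo < x[1] || hi > x[length(x)]) {
    stop_invalid(sprintf("region [%g, %g] outside axis [%g, %g]",
                         lo, hi, x[1], x[length(x)]))
  }
  cum <- cumtrapz0(x, y)
  ci <- stats::approx(x, cum, xout = c(lo, hi))$y
  ci[2] - ci[1]
}

# Evaluate code with a temporarily fixed RNG state; the caller's state is
# restored afterwards so simulation helpers do not perturb user code.
#' @keywords internal
#' @noRd
with_fixed_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# fftshift for even/odd lengths (move zero frequency to the centre).
#' @keywords internal
#' @noRd
fftshift1 <- function(x) {
  n <- length(x)
  k <- ceiling(n / 2)
  c(x[(k + 1):n], x[1:k])
}

#' @keywords internal
#' @noRd
ifftshift1 <- function(x) {
  n <- length(x)
  k <- floor(n / 2)
  c(x[(k + 1):n], x[1:k])
}
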