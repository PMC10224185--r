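#' Width in ppm occupied by a multiplet envelope
#'
#' Computes the spectral region occupied by an n-line multiplet with
#' scalar coupling `J_hz` when observed at a given spectrometer frequency,
#' using the convention `n_lines * J_hz / field_MHz`. Because J is fixed
#' in Hz while the ppm scale stretches with the spectrometer frequency,
#' the same multiplet occupies a far wider ppm range at 60 MHz than at
#' 800 MHz -- the root cause of low-field signal congestion.
#'
#' Note this is the multiplicity-times-J convention (3 x J for a triplet),
#' not the peak-to-peak span (n - 1) x J; the two differ by one J/field.
#'
#' @param J_hz Scalar coupling in Hz (>= 0).
#' @param n_lines Number of lines in the multiplet (>= 1).
#' @param field_MHz Spectrometer proton frequency in MHz (> 0).
#' @return Envelope width in ppm.
#' @examples
#' multiplet_envelope_ppm(7.70, 3, 60)   # 0.385 ppm, propionate CH3 triplet
#' multiplet_envelope_ppm(7.70, 3, 800)  # 0.0289 ppm at high field
#' @export
multiplet_envelope_ppm <- function(J_hz, n_lines, field_MHz) {
  if (!is_number(field_MHz) || field_MHz <= 0)
    stop_invalid("field_MHz must be a positive number")
  if (!is_number(J_hz) || J_hz < 0) stop_invalid("J_hz must be >= 0")
  if (!is_number(n_lines) || n_lines < 1) stop_invalid("n_lines must be >= 1")
  n_lines * J_hz / field_MHz
}

#' Construct a peak list
#'
#' A peak list holds the stick spectrum of a spin system at a given
#' spectrometer frequency: line positions in ppm and relative intensities
#' whose total equals the proton count of the source system (integrated
#' intensity is field independent).
#'
#' @param frequency_ppm Line positions in ppm.
#' @param intensity Non-negative line intensities.
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(frequency_ppm, intensity, field_MHz) {
  if (length(frequency_ppm) != length(intensity))
    stop_invalid("positions and intensities differ in length")
  if (any(intensity < -1e-12)) stop_invalid("intensities must be >= 0")
  o <- order(frequency_ppm)
  structure(list(frequency_ppm = as.numeric(frequency_ppm[o]),
                 intensity = pmax(as.numeric(intensity[o]), 0),
                 field_MHz = field_MHz),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", length(x$frequency_ppm), " lines at ", x$field_MHz,
      " MHz, total intensity ", format(sum(x$intensity)), "\n", sep = "")
  invisible(x)
}

# Merge lines closer than tol_hz, summing intensities (degenerate
# transitions collapse to one observed line).
#' @keywords internal
#' @noRd
merge_lines <- function(freq_hz, intensity, tol_hz = 1e-7) {
  o <- order(freq_hz)
  f <- freq_hz[o]; w <- intensity[o]
  grp <- cumsum(c(1, diff(f) > tol_hz))
  f2 <- as.numeric(tapply(f * w, grp, sum) / tapply(w, grp, sum))
  w2 <- as.numeric(tapply(w, grp, sum))
  list(freq_hz = f2, intensity = w2)
}

#' First-order (weak-coupling) multiplet pattern
#'
#' Renders the stick spectrum of a spin system under the first-order
#' approximation: each group of equivalent protons yields a multiplet
#' obtained by convolving, for every coupled partner group with n
#' equivalent protons, an (n+1)-line splitting with binomial intensities.
#' Line positions are `delta +/- k J / field` in ppm; the intensity of a
#' group's multiplet sums to its proton count. Valid when chemical-shift
#' separations in Hz are large compared to J (always a good approximation
#' at 800 MHz, often violated at 60 MHz -- see
#' [full_hamiltonian_peaks()]).
#'
#' @param system A [spin_system()].
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @return A [peak_list()].
#' @examples
#' aceta <- spin_system("acetate", 1.92, 3)
#' first_order_peaks(aceta, 60)  # one line at 1.92 ppm, intensity 3
#' @export
first_order_peaks <- function(system, field_MHz) {
  if (!is_number(field_MHz) || field_MHz <= 0)
    stop_invalid("field_MHz must be a positive number")
  k <- length(system$shifts_ppm)
  all_f <- numeric(0); all_w <- numeric(0)
  for (g in seq_len(k)) {
    f <- system$shifts_ppm[g] * field_MHz  # Hz
    w <- 1
    for (j in seq_len(k)) {
      J <- system$J_hz[g, j]
      if (j == g || J == 0) next
      nj <- system$n_protons[j]
      off <- (0:nj - nj / 2) * J
      bw <- choose(nj, 0:nj) / 2^nj
      f <- as.vector(outer(f, off, `+`))
      w <- as.vector(outer(w, bw, `*`))
    }
    m <- merge_lines(f, w)
    all_f <- c(all_f, m$freq_hz)
    all_w <- c(all_w, m$intensity * system$n_protons[g])
  }
  peak_list(all_f / field_MHz, all_w, field_MHz)
}

# Single-spin operators embedded in an N-spin product basis.
#' @keywords internal
#' @noRd
embed_op <- function(op, i, N) {
  m <- 1
  for (s in seq_len(N)) {
    m <- kronecker(m, if (s == i) op else diag(2))
  }
  m
}

#' Exact quantum-mechanical multiplet pattern
#'
#' Builds the isotropic liquid-state spin Hamiltonian (in Hz)
#' \deqn{H = \sum_i \nu_i I_{z,i} + \sum_{i<j} J_{ij}\, \mathbf{I}_i \cdot \mathbf{I}_j}
#' for the fully expanded spin system (each equivalent proton an explicit
#' spin-1/2 with identical shift), diagonalizes it, and emits all allowed
#' single-quantum transitions with intensities proportional to the squared
#' transverse transition moment, normalized so total intensity equals the
#' proton count. This reproduces strong-coupling (second-order) effects
#' such as AB roof patterns that dominate 60 MHz spectra, and converges to
#' the first-order pattern when shift separations in Hz dwarf J.
#'
#' The state space grows as 2^N; systems with more than `max_spins`
#' protons raise an error directing the caller to [first_order_peaks()].
#'
#' @param system A [spin_system()].
#' @param field_MHz Spectrometer proton frequency in MHz.
#' @param max_spins Cap on the expanded spin count (default 8).
#' @param intensity_floor Drop transitions weaker than this fraction of a
#'   proton (default 1e-12; weak combination lines above the floor are
#'   kept so total intensity is conserved).
#' @return A [peak_list()].
#' @export
full_hamiltonian_peaks <- function(system, field_MHz, max_spins = 8,
                                   intensity_floor = 1e-12) {
  if (!is_number(field_MHz) || field_MHz <= 0)
    stop_invalid("field_MHz must be a positive number")
  N <- sum(system$n_protons)
  if (N > max_spins) {
    stop(structure(class = c("benchnmr_size", "error", "condition"),
                   list(message = sprintf(
      "'%s' expands to %d spins (cap %d); use first_order_peaks() for this system",
      system$name, N, max_spins), call = sys.call())))
  }
  # expand equivalent groups into individual spins
  spin_shift <- rep(system$shifts_ppm, system$n_protons)
  spin_group <- rep(seq_along(system$n_protons), system$n_protons)
  nu <- spin_shift * field_MHz  # Hz

  Iz1 <- diag(c(0.5, -0.5))
  Ix1 <- matrix(c(0, 0.5, 0.5, 0), 2)
  Ip1 <- matrix(c(0, 0, 1, 0), 2)  # I+ : |beta> -> |alpha>
  Im1 <- t(Ip1)

  dim2 <- 2^N
  H <- matrix(0, dim2, dim2)
  Iz_list <- lapply(seq_len(N), function(i) embed_op(Iz1, i, N))
  for (i in seq_len(N)) H <- H + nu[i] * Iz_list[[i]]
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      J <- system$J_hz[spin_group[i], spin_group[j]]
      # equivalent spins within a group: coupling among them does not
      # affect the spectrum; any J value gives identical transitions, use 0
      if (spin_group[i] == spin_group[j]) J <- 0
      if (J == 0) next
      flip <- embed_op(Ip1, i, N) %*% embed_op(Im1, j, N)
      H <- H + J * (Iz_list[[i]] %*% Iz_list[[j]] + (flip + t(flip)) / 2)
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  V <- eig$vectors
  Ixt <- matrix(0, dim2, dim2)
  for (i in seq_len(N)) Ixt <- Ixt + embed_op(Ix1, i, N)
  M <- crossprod(V, Ixt %*% V)
  # intensity of transition a->b: 4 |<a|Ix|b>|^2 / 2^(N-1); total = N
  inten <- 4 * M^2 / 2^(N - 1)
  dE <- outer(eig$values, eig$values, `-`)
  keep <- upper.tri(dE) | lower.tri(dE)
  sel <- which(keep & dE > 0 & inten > intensity_floor, arr.ind = TRUE)
  if (nrow(sel) == 0) return(peak_list(numeric(0), numeric(0), field_MHz))
  m <- merge_lines(dE[sel], inten[sel], tol_hz = 1e-7)
  peak_list(m$freq_hz / field_MHz, m$intensity, field_MHz)
}
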