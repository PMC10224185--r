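#' Spectral binning scheme
#'
#' Uniform bins tiled half-open `[left, left + width)` from the range
#' start, with exclusion windows (residual water by default). A bin is
#' dropped when its center falls inside an exclusion window
#' (`rule = "center"`, default) or when it overlaps one at all
#' (`rule = "any-overlap"`). Since 4.5 and 5.0 ppm are not multiples of
#' 0.04, the center rule drops exactly the bins starting at 4.48 through
#' 4.96 under the defaults.
#'
#' @param width_ppm Bin width in ppm (default 0.04).
#' @param range_ppm Axis range covered (default `c(0, 10)`; the 0 edge is
#'   inclusive, the 10 edge exclusive).
#' @param exclusions List of `c(lo, hi)` ppm windows to drop (default
#'   residual water, `c(4.5, 5.0)`).
#' @param rule Exclusion rule, `"center"` or `"any-overlap"`.
#' @return A `binning_scheme` with precomputed edges, centers and the
#'   retained-bin index.
#' @export
binning_scheme <- function(width_ppm = 0.04, range_ppm = c(0, 10),
                           exclusions = list(c(4.5, 5.0)),
                           rule = c("center", "any-overlap")) {
  rule <- match.arg(rule)
  if (!is_number(width_ppm) || width_ppm <= 0) stop_invalid("width must be > 0")
  for (ex in exclusions) {
    if (ex[1] < range_ppm[1] || ex[2] > range_ppm[2])
      stop_invalid("exclusion window outside the binning range")
  }
  n <- floor((range_ppm[2] - range_ppm[1]) / width_ppm + 1e-9)
  left <- range_ppm[1] + (seq_len(n) - 1) * width_ppm
  center <- left + width_ppm / 2
  drop <- rep(FALSE, n)
  for (ex in exclusions) {
    drop <- drop | if (rule == "center") center >= ex[1] & center < ex[2]
                   else (left < ex[2]) & (left + width_ppm > ex[1])
  }
  structure(list(width_ppm = width_ppm, range_ppm = range_ppm,
                 exclusions = exclusions, rule = rule,
                 left_edges = left, centers = center, retained = !drop),
            class = "binning_scheme")
}

#' Bin one spectrum
#'
#' Integrates the spectrum (trapezoidal rule) over each retained bin.
#' Bin values are areas, not mean intensities: areas are what TSP
#' normalization preserves and what integrated-intensity comparisons
#' refer to.
#'
#' @param spectrum A TSP-normalized `nmr_spectrum` (set
#'   `allow_unnormalized = TRUE` to override the contract check).
#' @param scheme A [binning_scheme()].
#' @param allow_unnormalized Skip the normalization-state check.
#' @return Named numeric vector of bin areas (names = bin centers, 3 dp).
#' @export
bin_spectrum <- function(spectrum, scheme = binning_scheme(),
                         allow_unnormalized = FALSE) {
  if (!isTRUE(spectrum$meta$normalized) && !allow_unnormalized)
    stop_invalid("spectrum is not TSP-normalized; ",
                 "normalize first or set allow_unnormalized = TRUE")
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  edges <- c(scheme$left_edges, scheme$left_edges[length(scheme$left_edges)] +
               scheme$width_ppm)
  # clamp integration to the available axis: cumulative integral,
  # interpolated at the bin edges
  cum <- cumtrapz0(x, y)
  ce <- stats::approx(x, cum, xout = pmin(pmax(edges, x[1]), x[length(x)]))$y
  vals <- diff(ce)
  vals <- vals[scheme$retained]
  names(vals) <- sprintf("%.3f", scheme$centers[scheme$retained])
  vals
}

#' Assemble binned spectra into a sample-by-bin matrix
#'
#' @param vectors List of bin vectors from [bin_spectrum()], all under the
#'   same scheme.
#' @param labels Data frame with one row per vector (e.g. subject, group,
#'   day, field_MHz).
#' @param scheme The shared [binning_scheme()].
#' @return A `bin_matrix`: `values` (samples x retained bins, ascending
#'   ppm), `centers`, `labels`, `scheme`.
#' @export
assemble_bin_matrix <- function(vectors, labels, scheme = binning_scheme()) {
  if (length(vectors) != nrow(labels))
    stop_invalid("labels must have one row per bin vector")
  p <- sum(scheme$retained)
  expect_names <- sprintf("%.3f", scheme$centers[scheme$retained])
  for (v in vectors) {
    if (length(v) != p || !identical(names(v), expect_names))
      stop_invalid("bin vectors were not produced under the given scheme")
  }
  values <- do.call(rbind, vectors)
  rownames(values) <- NULL
  structure(list(values = values, centers = scheme$centers[scheme$retained],
                 labels = as.data.frame(labels), scheme = scheme),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d samples x %d bins (width %.3g ppm)\n",
              nrow(x$values), ncol(x$values), x$scheme$width_ppm))
  invisible(x)
}

#' Write a bin matrix to CSV
#'
#' Label columns first, then one column per bin named by its center to
#' three decimals. A comment header records the package version and,
#' when supplied, the simulation seed.
#'
#' @param bm A `bin_matrix`.
#' @param path Output file.
#' @param seed Optional seed to record in the header.
#' @export
write_bin_matrix_csv <- function(bm, path, seed = NULL) {
  df <- cbind(bm$labels,
              stats::setNames(as.data.frame(bm$values),
                              sprintf("%.3f", bm$centers)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a bin matrix written by [write_bin_matrix_csv()]
#'
#' @param path CSV file.
#' @param n_label_cols Number of leading label columns.
#' @return A list with `values`, `centers`, `labels` (scheme metadata is
#'   not reconstructed from CSV).
#' @export
read_bin_matrix_csv <- function(path, n_label_cols) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -seq_len(n_label_cols), drop = FALSE])
  list(values = unname(values),
       centers = as.numeric(colnames(df)[-seq_len(n_label_cols)]),
       labels = df[, seq_len(n_label_cols), drop = FALSE])
}

#' @keywords internal
#' @noRd
output_header <- function(seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("benchnmr")),
                  error = function(e) "dev")
  paste0("# benchnmr ", ver, if (!is.null(seed)) paste0(" seed=", seed))
}
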