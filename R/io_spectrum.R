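# Spectrum file I/O: JCAMP-DX (XYDATA) and plain two-column CSV.
# Vendor raw directories (Bruker/Magritek) are deliberately unsupported:
# their dialects are out of scope, and frequency-domain exchange formats
# cover the pipeline's needs.

#' Write a spectrum to JCAMP-DX
#'
#' Writes an `##XYDATA=(X++(Y..Y))` block in plain AFFN form with the
#' usual XFACTOR/YFACTOR scaling and the spectrometer frequency in
#' `##.OBSERVE FREQUENCY`.
#'
#' @param spectrum An `nmr_spectrum` (real part is written).
#' @param path Output file.
#' @param title Title record.
#' @export
write_jcampdx <- function(spectrum, path, title = "benchnmr spectrum") {
  x <- spectrum$ppm
  y <- Re(spectrum$intensity)
  yfac <- 1
  yi <- sprintf("%.12e", y)
  n <- length(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##DATA CLASS=XYDATA",
    paste0("##.OBSERVE FREQUENCY=", format(spectrum$field_MHz, digits = 12)),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    paste0("##XFACTOR=", format((x[n] - x[1]) / (n - 1), digits = 17)),
    paste0("##YFACTOR=", format(yfac, digits = 17)),
    paste0("##FIRSTX=", format(x[1], digits = 17)),
    paste0("##LASTX=", format(x[n], digits = 17)),
    paste0("##NPOINTS=", n),
    paste0("##FIRSTY=", format(y[1], digits = 17)),
    "##XYDATA=(X++(Y..Y))"), con)
  dx <- (x[n] - x[1]) / (n - 1)
  idx <- seq(1, n, by = 8)
  lines <- vapply(idx, function(i) {
    j <- min(i + 7, n)
    paste(c(format((x[i] - x[1]) / dx, digits = 12), yi[i:j]), collapse = " ")
  }, "")
  writeLines(lines, con)
  writeLines("##END=", con)
  invisible(path)
}

# Tokenize one JCAMP ASDF data line into numbers, honouring AFFN/PAC,
# SQZ (@A-I/a-i), DIF (%J-R/j-r) and DUP (S-Zs) pseudo-digits.
#' @keywords internal
#' @noRd
parse_asdf_line <- function(line, prev_y, lineno) {
  toks <- regmatches(line, gregexpr(
    "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?|[@A-Za-z%][0-9]*\\.?[0-9]*", line))[[1]]
  if (!length(toks)) return(list(x = NA_real_, y = numeric(0), last = prev_y))
  sqz_pos <- c(`@` = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7, H = 8, I = 9)
  sqz_neg <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6, g = 7, h = 8, i = 9)
  dif_pos <- c(`%` = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7, Q = 8, R = 9)
  dif_neg <- c(j = 1, k = 2, l = 3, m = 4, n = 5, o = 6, p = 7, q = 8, r = 9)
  dup <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)
  decode <- function(tok) {
    first <- substr(tok, 1, 1)
    rest <- substr(tok, 2, nchar(tok))
    if (first %in% names(sqz_pos))
      list(mode = "y", val = as.numeric(paste0(sqz_pos[[first]], rest)))
    else if (first %in% names(sqz_neg))
      list(mode = "y", val = -as.numeric(paste0(sqz_neg[[first]], rest)))
    else if (first %in% names(dif_pos))
      list(mode = "dif", val = as.numeric(paste0(dif_pos[[first]], rest)))
    else if (first %in% names(dif_neg))
      list(mode = "dif", val = -as.numeric(paste0(dif_neg[[first]], rest)))
    else if (first %in% names(dup))
      list(mode = "dup", val = as.numeric(paste0(dup[[first]], rest)))
    else list(mode = "y", val = suppressWarnings(as.numeric(tok)))
  }
  xval <- suppressWarnings(as.numeric(toks[1]))
  if (is.na(xval))
    stop("JCAMP parse error at line ", lineno, ": data line lacks abscissa")
  ys <- numeric(0)
  last <- prev_y
  last_tok <- NULL
  for (tok in toks[-1]) {
    d <- decode(tok)
    if (is.na(d$val)) stop("JCAMP parse error at line ", lineno, ": '", tok, "'")
    if (d$mode == "dup") {
      if (is.null(last_tok)) stop("JCAMP parse error at line ", lineno,
                                  ": DUP with no preceding value")
      for (z in seq_len(d$val - 1)) {
        if (last_tok$mode == "dif") last <- last + last_tok$val
        ys <- c(ys, last)
      }
    } else {
      last <- if (d$mode == "dif") last + d$val else d$val
      ys <- c(ys, last)
      last_tok <- d
    }
  }
  list(x = xval, y = ys, last = last,
       dif_ended = !is.null(last_tok) && last_tok$mode == "dif")
}

#' Read a JCAMP-DX spectrum
#'
#' Parses a frequency-domain `##XYDATA=(X++(Y..Y))` block; AFFN/PAC plus
#' SQZ/DIF/DUP compressed forms are supported. The axis is normalized to
#' ascending ppm.
#'
#' @param path JCAMP-DX file.
#' @return An `nmr_spectrum`.
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    pat <- paste0("^##\\.?", key, "=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA)
    trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  }
  need <- function(key) {
    v <- suppressWarnings(as.numeric(hdr(key)))
    if (is.na(v)) {
      ln <- grep(paste0("^##\\.?", key), lines, ignore.case = TRUE)
      stop("JCAMP parse error: missing or malformed ##", key,
           if (length(ln)) paste0(" at line ", ln[1]) else "")
    }
    v
  }
  npoints <- need("NPOINTS")
  xfac <- need("XFACTOR"); yfac <- need("YFACTOR")
  firstx <- need("FIRSTX"); lastx <- need("LASTX")
  field <- suppressWarnings(as.numeric(hdr("OBSERVE FREQUENCY")))
  if (is.na(field)) field <- NA_real_
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("JCAMP parse error: no ##XYDATA block")
  endln <- grep("^##END", lines)
  endln <- if (length(endln)) min(endln[endln > start[1]]) else length(lines) + 1
  ys <- numeric(0)
  prev <- NA_real_
  dif_pending <- FALSE
  for (ln in seq(start[1] + 1, endln - 1)) {
    row <- parse_asdf_line(lines[ln], prev, ln)
    yrow <- row$y
    # in DIF form each line starts with a check value repeating the last
    # Y of the previous line
    if (dif_pending && length(yrow)) yrow <- yrow[-1]
    ys <- c(ys, yrow)
    prev <- row$last
    dif_pending <- isTRUE(row$dif_ended)
  }
  if (length(ys) != npoints)
    stop("JCAMP parse error: expected ", npoints, " points, found ",
         length(ys), " (truncated file?)")
  x <- seq(firstx, lastx, length.out = npoints)
  nmr_spectrum(x, ys * yfac, field, meta = list(source = path, xfactor = xfac))
}

#' Write a spectrum to two-column CSV
#'
#' Columns `ppm,intensity`, preceded by a `#` comment header carrying
#' the package version (and seed when given).
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output file.
#' @param seed Optional seed recorded in the header.
#' @export
write_spectrum_csv <- function(spectrum, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(output_header(seed),
               paste0("# field_MHz=", format(spectrum$field_MHz, digits = 12)),
               "ppm,intensity"), con)
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = Re(spectrum$intensity)),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column CSV spectrum
#'
#' Accepts `ppm,intensity` rows with optional header line and `#`
#' comments; a descending ppm axis is normalized to ascending.
#'
#' @param path CSV file.
#' @param field_MHz Spectrometer frequency; when `NA`, taken from a
#'   `# field_MHz=` comment if present.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum_csv <- function(path, field_MHz = NA) {
  lines <- readLines(path, warn = FALSE)
  if (is.na(field_MHz)) {
    fl <- grep("^#\\s*field_MHz=", lines, value = TRUE)
    if (length(fl)) field_MHz <- as.numeric(sub("^#\\s*field_MHz=", "", fl[1]))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) && grepl("[A-Za-z]", strsplit(body[1], ",")[[1]][1]))
    body <- body[-1]
  if (!length(body)) stop("CSV parse error: no data rows in ", path)
  parts <- strsplit(body, ",")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop("CSV parse error at data row ", bad[1], ": expected ppm,intensity")
  x <- as.numeric(vapply(parts, `[`, "", 1))
  y <- as.numeric(vapply(parts, `[`, "", 2))
  if (anyNA(x) || anyNA(y))
    stop("CSV parse error: non-numeric values in ", path)
  nmr_spectrum(x, y, field_MHz, meta = list(source = path))
}

#' Read a spectrum, dispatching on file extension
#' @param path `.jdx`/`.dx` (JCAMP-DX) or `.csv` file.
#' @param ... Passed to the format reader.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path, ...) {
  if (grepl("\\.(jdx|dx|jcm)$", path, ignore.case = TRUE)) read_jcampdx(path)
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) read_spectrum_csv(path, ...)
  else stop_invalid("unsupported spectrum format: ", path)
}

#' Write a spectrum, dispatching on file extension
#' @param spectrum An `nmr_spectrum`.
#' @param path Destination (`.jdx`/`.dx` or `.csv`).
#' @param ... Passed to the format writer.
#' @export
write_spectrum <- function(spectrum, path, ...) {
  if (grepl("\\.(jdx|dx|jcm)$", path, ignore.case = TRUE))
    write_jcampdx(spectrum, path, ...)
  else if (grepl("\\.csv$", path, ignore.case = TRUE))
    write_spectrum_csv(spectrum, path, ...)
  else stop_invalid("unsupported spectrum format: ", path)
}
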