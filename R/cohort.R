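# Synthetic cohort generation: two groups x n subjects x days, with
# DSS-direction fold changes applied to the treated group and lognormal
# between-sample biological variation.

#' Cohort design
#'
#' Describes the synthetic study layout and the metabolite concentration
#' model. Defaults are read from the shipped design file
#' (`inst/extdata/default_design.yaml`): 2 groups (control, DSS) x 3
#' subjects x days 0-5, biological CV 20\%, internal standards TSP
#' 0.5 mM and formate-spike 1 mM, and fold-change directions matching the
#' colitis phenotype (acetate, succinate, glucose, taurine up; butyrate,
#' propionate, branched-chain amino acids, leucine, alanine, aspartate,
#' glycerol, threonine down). Fold changes ramp geometrically from the
#' onset day (default 2) to day 5, so treated and control groups are
#' indistinguishable through day 2 and fully shifted at day 5.
#'
#' @param path YAML design file (default the shipped one).
#' @param ... Named overrides of top-level design fields
#'   (`n_per_group`, `days`, `cv_biological`, `onset_day`, `noise_snr`,
#'   `baseline_mM`, `fold_day5`, ...).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(path = system.file("extdata", "default_design.yaml",
                                             package = "benchnmr",
                                             mustWork = TRUE), ...) {
  d <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d$days <- as.numeric(d$days)
  d$baseline_mM <- unlist(d$baseline_mM)
  d$fold_day5 <- unlist(d$fold_day5)
  if (any(d$baseline_mM <= 0)) stop_invalid("baseline concentrations must be > 0")
  if (any(d$fold_day5 <= 0)) stop_invalid("fold changes must be > 0")
  structure(d, class = "cohort_design")
}

#' Fold change of a metabolite at a given day
#'
#' Control samples have fold 1 on every day. Treated (DSS) samples have
#' fold 1 before the onset day; from the onset day the log-fold follows
#' a saturating ramp to its final-day value,
#' `fold(day) = fold_day5 ^ sqrt((day - onset + 1)/(last - onset + 1))`,
#' so a partial effect is already present on the onset day and most of
#' the shift is established one day later -- the treated group separates
#' partially at onset and fully thereafter, while day 0 always has
#' fold 1.
#'
#' @param design A [cohort_design()].
#' @param metabolite Metabolite name.
#' @param group `"control"` or the treated-group label (`"DSS"`).
#' @param day Study day.
#' @return Multiplicative fold change.
#' @export
fold_for_day <- function(design, metabolite, group, day) {
  if (group == "control") return(1)
  f5 <- unname(design$fold_day5[metabolite])
  if (is.null(f5) || is.na(f5)) f5 <- 1
  last <- max(design$days)
  if (day < design$onset_day) return(1)
  ramp <- sqrt((day - design$onset_day + 1) / (last - design$onset_day + 1))
  f5^min(ramp, 1)
}

#' Draw one sample's concentration profile
#'
#' Lognormal draw per metabolite around `baseline * fold(group, day)`
#' with the configured biological coefficient of variation: the lognormal
#' parameters are moment-matched so the arithmetic mean equals the target
#' and `sd/mean = cv`. Internal standards (TSP, formate spike) are pipetted,
#' not biological, and carry no variation; formate's biological
#' component varies and its 1 mM spike is added on top.
#'
#' @param design A [cohort_design()].
#' @param subject Subject index (1-based within group).
#' @param group `"control"` or `"DSS"`.
#' @param day Study day (must be in `design$days`).
#' @return Named numeric vector of concentrations in mM.
#' @export
sample_concentrations <- function(design, subject, group, day) {
  if (!day %in% design$days) stop_invalid("day not in design")
  if (subject < 1 || subject > design$n_per_group)
    stop_invalid("subject index outside design")
  mets <- names(design$baseline_mM)
  cv <- design$cv_biological
  out <- vapply(mets, function(m) {
    target <- design$baseline_mM[[m]] * fold_for_day(design, m, group, day)
    if (cv <= 0) return(target)
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, log(target) - sdlog^2 / 2, sdlog)
  }, 0)
  out[["TSP"]] <- design$tsp_mM
  out[["formate"]] <- out[["formate"]] + design$formate_spike_mM
  out
}

# Cache of unit-concentration (1 mM) metabolite spectra per
# (field, grid, lineshape, library) combination; concentrations only
# scale these bases, so a cohort render is a weighted sum plus noise.
.basis_cache <- new.env(parent = emptyenv())

#' @keywords internal
#' @noRd
metabolite_basis <- function(library, field_MHz, axis, shape,
                             mode = c("first_order", "hamiltonian")) {
  mode <- match.arg(mode)
  key <- paste(field_MHz, length(axis), axis[1], axis[length(axis)],
               shape$width_hz, shape$eta, mode,
               paste(names(library), collapse = ","), sep = "|")
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  shape0 <- shape; shape0$noise_sd <- 0; shape0$baseline_coeffs <- 0
  basis <- vapply(library, function(sys) {
    pk <- if (mode == "hamiltonian" && sum(sys$n_protons) <= 8)
      full_hamiltonian_peaks(sys, field_MHz) else first_order_peaks(sys, field_MHz)
    render_spectrum(pk, axis, shape0)$intensity
  }, numeric(length(axis)))
  .basis_cache[[key]] <- basis
  basis
}

#' Synthesize a full cohort of spectra with known ground truth
#'
#' For every subject x day x field, draws a concentration profile,
#' renders the weighted sum of per-metabolite spectra (internal
#' standards included) on the default grid for that field, and adds
#' seeded frequency-domain noise scaled so the strongest line of the
#' mean control profile has the design's peak signal-to-noise ratio.
#' Per-metabolite spectra are rendered once per field at 1 mM and reused
#' across samples (concentrations enter linearly), so chemical shifts do
#' not vary between samples.
#'
#' @param design A [cohort_design()].
#' @param library Metabolite library from [read_metabolite_library()];
#'   must cover every metabolite in the design.
#' @param fields Numeric vector of spectrometer frequencies in MHz.
#' @param seed RNG seed; the full output is reproducible from
#'   `(design, seed)`.
#' @param mode Simulation mode for the multiplet patterns
#'   (`"first_order"` default; `"hamiltonian"` where tractable).
#' @return List with `spectra` (list over fields of lists of
#'   `nmr_spectrum`), `truth` (data frame: subject, group, day,
#'   metabolite, true_concentration_mM), `labels` (one row per sample).
#' @export
synthesize_cohort <- function(design, library = read_metabolite_library(),
                              fields = c(60, 800), seed = 1,
                              mode = "first_order") {
  if (length(fields) == 0) stop_invalid("field list must not be empty")
  mets <- unique(c(names(design$baseline_mM), "TSP"))
  missing <- setdiff(mets, names(library))
  if (length(missing))
    stop_invalid("library does not cover: ", paste(missing, collapse = ", "))
  library <- library[mets]

  groups <- c("control", "DSS")
  labels <- expand.grid(subject = seq_len(design$n_per_group),
                        day = design$days, group = groups,
                        stringsAsFactors = FALSE)
  labels <- labels[order(labels$group, labels$subject, labels$day), ]
  rownames(labels) <- NULL

  with_fixed_seed(seed, {
    conc <- lapply(seq_len(nrow(labels)), function(i) {
      sample_concentrations(design, labels$subject[i], labels$group[i],
                            labels$day[i])
    })
    truth <- do.call(rbind, lapply(seq_len(nrow(labels)), function(i) {
      data.frame(subject = labels$subject[i], group = labels$group[i],
                 day = labels$day[i], metabolite = names(conc[[i]]),
                 true_concentration_mM = unname(conc[[i]]),
                 row.names = NULL)
    }))
    spectra <- lapply(fields, function(fld) {
      axis <- default_grid(fld)
      shape <- default_lineshape(fld)
      basis <- metabolite_basis(library, fld, axis, shape, mode)
      # noise floor anchored to the strongest line of the mean profile
      bc <- design$baseline_mM
      bc[["TSP"]] <- design$tsp_mM
      bc[["formate"]] <- bc[["formate"]] + design$formate_spike_mM
      mean_y <- as.numeric(basis %*% bc[colnames(basis)])
      noise_sd <- if (design$noise_snr > 0) max(mean_y) / design$noise_snr else 0
      lapply(seq_len(nrow(labels)), function(i) {
        y <- as.numeric(basis %*% conc[[i]][colnames(basis)])
        if (noise_sd > 0) y <- y + stats::rnorm(length(axis), 0, noise_sd)
        nmr_spectrum(axis, y, fld,
                     meta = list(normalized = FALSE,
                                 subject = labels$subject[i],
                                 group = labels$group[i], day = labels$day[i],
                                 acquisition = if (fld < 200) "PRESAT"
                                               else "zgpr"))
      })
    })
    names(spectra) <- as.character(fields)
    list(spectra = spectra, truth = truth, labels = labels)
  })
}
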