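# End-to-end reproducible runs: synthesize -> process -> bin -> PCA /
# OPLS-DA -> quantify -> report, with all outputs (tables as CSV, model
# summaries as JSON, figures as data-backed SVG) under one run directory.

#' Pipeline run configuration
#'
#' @param seed Global RNG seed.
#' @param fields Spectrometer frequencies simulated (MHz).
#' @param out_dir Run directory (created if absent).
#' @param design_overrides Named list passed to [cohort_design()].
#' @param days_multivariate Days entering PCA/OPLS-DA (default 2-5;
#'   the full-course view is also supported by passing `0:5`).
#' @param scaling Bin-matrix scaling for multivariate analysis
#'   (`"pareto"` default).
#' @param n_ortho,cv_folds OPLS-DA settings.
#' @param snr_calibration Peak SNR of the calibration standards
#'   (`NULL` = per-field default, see [acetate_calibration()]).
#' @param quant_methods Quantification strategies run at low field.
#' @param figures Emit SVG figures (default `TRUE`; data tables are
#'   always written).
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1, fields = c(60, 800), out_dir = tempfile("run"),
                       design_overrides = list(), days_multivariate = 2:5,
                       scaling = "pareto", n_ortho = 1, cv_folds = 7,
                       snr_calibration = NULL,
                       quant_methods = c("region", "gl", "library"),
                       figures = TRUE) {
  cfg <- as.list(environment())
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop_invalid("unknown config key: ", extra[1])
  structure(cfg, class = "run_config")
}

#' @keywords internal
#' @noRd
validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) {
    known <- names(formals(run_config))
    extra <- setdiff(names(config), known)
    if (length(extra)) stop_invalid("unknown config key: ", extra[1])
    config <- do.call(run_config, config)
  }
  config
}

#' @keywords internal
#' @noRd
stage <- function(name, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(code), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' @keywords internal
#' @noRd
try_svg <- function(path, width, height, plot_fun) {
  ok <- tryCatch({
    grDevices::svg(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    plot_fun()
    TRUE
  }, error = function(e) {
    warning("figure skipped (", conditionMessage(e), ")")
    FALSE
  })
  invisible(ok)
}

#' Run the full analysis pipeline
#'
#' Synthesizes the cohort at every configured field, normalizes and bins
#' each spectrum, fits PCA and OPLS-DA on the configured day range,
#' builds calibration curves, quantifies acetate at low field by the
#' configured strategies with the high-field library fit as reference,
#' computes method-agreement statistics and the per-day group
#' comparison, and writes everything (plus the resolved configuration)
#' under `config$out_dir`. Deterministic given the seed.
#'
#' @param config A [run_config()] (or plain list of its fields).
#' @return Invisibly, a list with the key objects (`cohort`,
#'   `bin_matrices`, `pca`, `opls`, `quant`, `agreement`, `welch_day5`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = run_config()) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  lib <- read_metabolite_library()

  design <- do.call(cohort_design, config$design_overrides)
  cohort <- stage("simulate", synthesize_cohort(design, lib,
                                                fields = config$fields,
                                                seed = seed))
  utils::write.csv(cohort$truth,
                   file.path(config$out_dir, "ground_truth.csv"),
                   row.names = FALSE)

  scheme <- binning_scheme()
  processed <- list(); bms <- list()
  for (fld in as.character(config$fields)) {
    processed[[fld]] <- stage(paste0("process@", fld), lapply(
      cohort$spectra[[fld]], reference_and_normalize))
    vecs <- lapply(processed[[fld]], bin_spectrum, scheme = scheme)
    bms[[fld]] <- assemble_bin_matrix(vecs, cohort$labels, scheme)
    write_bin_matrix_csv(bms[[fld]],
                         file.path(config$out_dir,
                                   paste0("bin_matrix_", fld, ".csv")),
                         seed = seed)
  }

  sub <- cohort$labels$day %in% config$days_multivariate
  pca <- list(); opls <- list()
  for (fld in as.character(config$fields)) {
    X <- bms[[fld]]$values[sub, , drop = FALSE]
    sc <- scale_columns(X, config$scaling)
    pca[[fld]] <- fit_pca(sc, 2)
    opls[[fld]] <- fit_oplsda(sc, cohort$labels$group[sub],
                              n_ortho = config$n_ortho,
                              cv_folds = config$cv_folds,
                              positive_class = "DSS")
    sl <- s_line(opls[[fld]], bms[[fld]]$centers)
    sl$vip <- opls[[fld]]$vip
    utils::write.csv(sl, file.path(config$out_dir,
                                   paste0("sline_vip_", fld, ".csv")),
                     row.names = FALSE)
    scores_df <- data.frame(cohort$labels[sub, ],
                            pc1 = pca[[fld]]$scores[, 1],
                            pc2 = pca[[fld]]$scores[, 2],
                            opls_score = opls[[fld]]$scores)
    utils::write.csv(scores_df, file.path(config$out_dir,
                                          paste0("scores_", fld, ".csv")),
                     row.names = FALSE)
    if (isTRUE(config$figures)) {
      try_svg(file.path(config$out_dir, paste0("scores_", fld, ".svg")), 7, 6,
              function() {
        cols <- ifelse(scores_df$group == "DSS", "red3", "blue3")
        graphics::plot(scores_df$pc1, scores_df$pc2, col = cols, pch = 19,
                       xlab = sprintf("PC1 (%.1f%%)",
                         100 * pca[[fld]]$explained_variance_fraction[1]),
                       ylab = sprintf("PC2 (%.1f%%)",
                         100 * pca[[fld]]$explained_variance_fraction[2]),
                       main = paste0("PCA scores, ", fld, " MHz"))
        graphics::legend("topright", c("control", "DSS"), pch = 19,
                         col = c("blue3", "red3"))
      })
      try_svg(file.path(config$out_dir, paste0("sline_", fld, ".svg")), 8, 5,
              function() {
        graphics::plot(sl$ppm, sl$covariance, type = "h",
                       col = grDevices::hcl.colors(100, "viridis")[
                         pmax(1, ceiling(abs(sl$correlation) * 100))],
                       xlim = rev(range(sl$ppm)), xlab = "ppm",
                       ylab = "covariance with predictive score",
                       main = paste0("S-line, ", fld, " MHz"))
      })
    }
  }

  summ <- lapply(as.character(config$fields), function(fld) {
    list(field_MHz = as.numeric(fld),
         pca_explained = pca[[fld]]$explained_variance_fraction,
         R2X = opls[[fld]]$R2X, R2Y = opls[[fld]]$R2Y, Q2 = opls[[fld]]$Q2,
         n_ortho = config$n_ortho, cv_folds = config$cv_folds)
  })
  jsonlite::write_json(list(seed = seed, models = summ),
                       file.path(config$out_dir, "multivariate_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  lowf <- as.character(min(config$fields))
  highf <- as.character(max(config$fields))
  quant <- stage("quantify", {
    out <- list()
    for (m in config$quant_methods) {
      cal <- acetate_calibration(as.numeric(lowf), m, snr = config$snr_calibration,
                                 seed = seed + 101, library = lib)
      out[[paste0(m, "_", lowf)]] <- quantify_acetate(
        processed[[lowf]], m, cal, library = lib)
    }
    if (highf != lowf) {
      cal_ref <- acetate_calibration(as.numeric(highf), "library",
                                     snr = config$snr_calibration,
                                     seed = seed + 102, library = lib)
      out[["reference"]] <- quantify_acetate(processed[[highf]], "library",
                                             cal_ref, library = lib)
    }
    out
  })
  truth_acetate <- cohort$truth[cohort$truth$metabolite == "acetate", ]
  qdf <- data.frame(cohort$labels,
                    true_mM = truth_acetate$true_concentration_mM)
  for (nm in names(quant)) qdf[[nm]] <- quant[[nm]]
  utils::write.csv(qdf, file.path(config$out_dir, "acetate_quantification.csv"),
                   row.names = FALSE)

  agreement <- NULL
  if ("reference" %in% names(quant)) {
    agreement <- lapply(setdiff(names(quant), "reference"), function(nm) {
      a <- method_agreement(quant[[nm]], quant$reference)
      c(list(method = nm), a[c("n", "mean", "sd", "se", "ci95_lo", "ci95_hi",
                               "mae")],
        list(mape = mean(a$absolute_percentage_errors)))
    })
    jsonlite::write_json(agreement,
                         file.path(config$out_dir, "method_agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    ape <- do.call(rbind, lapply(setdiff(names(quant), "reference"),
      function(nm) data.frame(method = nm,
        abs_pct_error = method_agreement(quant[[nm]],
          quant$reference)$absolute_percentage_errors)))
    utils::write.csv(ape, file.path(config$out_dir, "agreement_boxplot.csv"),
                     row.names = FALSE)
  }

  gl_name <- if ("gl" %in% config$quant_methods)
    paste0("gl_", lowf) else names(quant)[1]
  byday <- stats::aggregate(qdf[[gl_name]],
                            by = list(group = qdf$group, day = qdf$day), mean)
  names(byday)[3] <- "mean_mM"
  utils::write.csv(byday, file.path(config$out_dir,
                                    "acetate_by_day.csv"), row.names = FALSE)
  last_day <- max(cohort$labels$day)
  ld <- qdf$day == last_day
  welch <- compare_groups(qdf[[gl_name]][ld], qdf$group[ld], "welch",
                          alternative = "two.sided")

  resolved <- config
  resolved$out_dir <- NULL
  yaml::write_yaml(resolved, file.path(config$out_dir, "resolved_config.yaml"))

  invisible(list(cohort = cohort, bin_matrices = bms, pca = pca, opls = opls,
                 quant = quant, agreement = agreement, welch_day5 = welch,
                 out_dir = config$out_dir))
}
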