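#' Column scaling for multivariate analysis
#'
#' Centers each column and scales it according to `mode`: Pareto scaling
#' divides by the square root of the column standard deviation (damping
#' dominance of intense bins without inflating noise bins as much as unit
#' variance does), `"uv"` divides by the standard deviation, `"none"`
#' centers only. Zero-variance columns are centered only and listed in
#' `zero_variance`.
#'
#' @param x Numeric matrix (samples x variables), at least 2 rows.
#' @param mode `"pareto"`, `"uv"` or `"none"`.
#' @return A `scaled_matrix`: `values`, `center`, `scale`, `mode`,
#'   `zero_variance` (column indices).
#' @export
scale_columns <- function(x, mode = c("pareto", "uv", "none")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_invalid("scaling needs at least 2 rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zv <- which(sdv == 0)
  sc <- switch(mode, pareto = sqrt(sdv), uv = sdv, none = rep(1, ncol(x)))
  sc[sc == 0] <- 1
  if (length(zv) && mode != "none")
    warning(length(zv), " zero-variance column(s) centered only")
  vals <- sweep(sweep(x, 2, mu), 2, sc, "/")
  structure(list(values = vals, center = mu, scale = sc, mode = mode,
                 zero_variance = zv),
            class = "scaled_matrix")
}

#' Undo scaling
#' @param sm A `scaled_matrix`.
#' @return The original data matrix.
#' @export
unscale <- function(sm) {
  sweep(sweep(sm$values, 2, sm$scale, "*"), 2, sm$center, "+")
}

#' Principal component analysis by NIPALS
#'
#' Fits successive rank-one approximations to the (scaled) data matrix by
#' the iterative NIPALS algorithm, deflating after each component.
#' Explained variance fractions are component sums of squares over the
#' total sum of squares.
#'
#' @param x A `scaled_matrix` or plain numeric matrix (rows = samples).
#' @param n_components Number of components (`<= min(nrow - 1, ncol)`).
#' @param tol,max_iter NIPALS convergence controls.
#' @return A `pca_model`: `scores` (n x k), `loadings` (p x k,
#'   orthonormal), `explained_variance_fraction`.
#' @export
fit_pca <- function(x, n_components = 2, tol = 1e-12, max_iter = 20000) {
  X <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p))
    stop_invalid("n_components exceeds min(rows - 1, cols)")
  total_ss <- sum(X^2)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  evf <- numeric(n_components)
  for (k in seq_len(n_components)) {
    t_vec <- X[, which.max(colSums(X^2))]
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(X, t_vec)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- X %*% p_vec
      if (sum((t_new - t_vec)^2) < tol^2 * sum(t_new^2)) { t_vec <- t_new; break }
      t_vec <- t_new
    }
    scores[, k] <- t_vec
    loadings[, k] <- p_vec
    evf[k] <- sum(t_vec^2) / total_ss
    X <- X - tcrossprod(t_vec, p_vec)
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", ncol(x$scores), " components; explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Core O-PLS fit on a centered/scaled X and centered y. Returns the
# predictive component (w, t, p, q) and n_ortho orthogonal components.
#' @keywords internal
#' @noRd
opls_core <- function(X, y, n_ortho) {
  W_o <- P_o <- NULL
  T_o <- NULL
  for (k in seq_len(n_ortho)) {
    w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
    t_vec <- X %*% w
    p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
    w_o <- p_vec - as.numeric(crossprod(w, p_vec)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- X %*% w_o
    p_ovec <- crossprod(X, t_o) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_ovec)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_ovec)
    T_o <- cbind(T_o, t_o)
  }
  w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
  t_vec <- X %*% w
  p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
  q <- as.numeric(crossprod(y, t_vec) / sum(t_vec^2))
  list(w = as.numeric(w), t = as.numeric(t_vec), p = as.numeric(p_vec), q = q,
       W_o = W_o, P_o = P_o, T_o = T_o, X_deflated = X)
}

# Project new (scaled, centered) rows through a fitted O-PLS model:
# strip orthogonal variation, then score on the predictive weights.
#' @keywords internal
#' @noRd
opls_project <- function(fit, Xnew) {
  if (!is.null(fit$W_o)) {
    for (k in seq_len(ncol(fit$W_o))) {
      t_o <- Xnew %*% fit$W_o[, k]
      Xnew <- Xnew - tcrossprod(t_o, fit$P_o[, k])
    }
  }
  as.numeric(Xnew %*% fit$w)
}

#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis:
#' variation in X orthogonal to the class response is split off into
#' `n_ortho` orthogonal components, then a single predictive PLS
#' component is fitted on the deflated matrix. The class vector is coded
#' +1/-1 and centered; the predictive component is oriented so the
#' `positive_class` mean score is positive, making S-line signs
#' reproducible.
#'
#' Model diagnostics follow chemometrics convention: R2X is the fraction
#' of X sum of squares captured by all components, R2Y the fraction of y
#' variance captured by the predictive component, and Q2 the
#' cross-validated predictability 1 - PRESS/SS from k-fold
#' cross-validation with deterministic venetian-blind fold assignment
#' (sample i in fold `(i - 1) mod k + 1`, in row order).
#'
#' @param x A `scaled_matrix` or numeric matrix (already scaled; rows =
#'   samples). Cross-validation refits on row subsets of this matrix.
#' @param y Two-level factor/character/numeric class labels.
#' @param n_ortho Number of orthogonal components (default 1).
#' @param cv_folds Cross-validation folds (default 7, capped at n).
#' @param positive_class Label mapped to +1 (default the second sorted
#'   unique level, e.g. "DSS" over "control").
#' @param folds Optional explicit fold-assignment integer vector
#'   overriding venetian blinds.
#' @return An `opls_model` with predictive weights/scores/loadings,
#'   orthogonal components, `R2X`, `R2Y`, `Q2`, `vip`, `s_covariance`,
#'   `s_correlation`.
#' @export
fit_oplsda <- function(x, y, n_ortho = 1, cv_folds = 7,
                       positive_class = NULL, folds = NULL) {
  X <- if (inherits(x, "scaled_matrix")) x$values else as.matrix(x)
  n <- nrow(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stop_invalid("OPLS-DA needs exactly 2 classes")
  if (is.null(positive_class)) positive_class <- lev[2]
  if (!positive_class %in% lev) stop_invalid("positive_class not among labels")
  if (min(table(y)) < 2) stop_invalid("each class needs >= 2 members for CV")
  yy <- ifelse(as.character(y) == positive_class, 1, -1)
  yc <- yy - mean(yy)
  ss_x <- sum(X^2); ss_y <- sum(yc^2)

  fit <- opls_core(X, yc, n_ortho)
  # orient predictive component toward the positive class
  if (mean(fit$t[yy == 1]) < mean(fit$t[yy == -1])) {
    fit$w <- -fit$w; fit$t <- -fit$t; fit$p <- -fit$p; fit$q <- -fit$q
  }
  yhat <- fit$t * fit$q
  R2Y <- 1 - sum((yc - yhat)^2) / ss_y
  ss_model <- sum(tcrossprod(fit$t, fit$p)^2)
  if (!is.null(fit$T_o)) {
    for (k in seq_len(ncol(fit$T_o)))
      ss_model <- ss_model + sum(tcrossprod(fit$T_o[, k], fit$P_o[, k])^2)
  }
  R2X <- ss_model / ss_x

  # cross-validated Q2
  cv_folds <- min(cv_folds, n)
  if (is.null(folds)) folds <- ((seq_len(n) - 1) %% cv_folds) + 1
  press <- 0
  for (f in sort(unique(folds))) {
    hold <- folds == f
    if (all(hold) || !any(hold)) next
    ytr <- yc[!hold]
    cvfit <- opls_core(X[!hold, , drop = FALSE], ytr, n_ortho)
    pred <- opls_project(cvfit, X[hold, , drop = FALSE]) * cvfit$q
    press <- press + sum((yc[hold] - pred)^2)
  }
  Q2 <- 1 - press / ss_y

  p_var <- ncol(X)
  vip <- sqrt(p_var) * abs(fit$w) / sqrt(sum(fit$w^2))
  s_cov <- as.numeric(crossprod(X, fit$t)) / (n - 1)
  tsd <- stats::sd(fit$t)
  xsd <- apply(X, 2, stats::sd)
  s_cor <- ifelse(xsd > 0, s_cov / (tsd * xsd), 0)

  structure(list(weights = fit$w, scores = fit$t, loadings = fit$p, q = fit$q,
                 ortho_weights = fit$W_o, ortho_scores = fit$T_o,
                 ortho_loadings = fit$P_o,
                 R2X = R2X, R2Y = R2Y, Q2 = Q2,
                 vip = vip, s_covariance = s_cov, s_correlation = s_cor,
                 y = yy, positive_class = positive_class,
                 classes = lev, n_ortho = n_ortho, cv_folds = cv_folds),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> 1 predictive + %d orthogonal; R2X %.3f, R2Y %.3f, Q2 %.3f\n",
    x$n_ortho, x$R2X, x$R2Y, x$Q2))
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection for the single predictive
#' component: `VIP_j = sqrt(p) |w_j| / ||w||`. The mean squared VIP is 1
#' by construction, and `VIP > 1` is the conventional selection rule,
#' exposed via `threshold`.
#'
#' @param model An `opls_model`.
#' @param threshold If non-`NULL`, return the logical selection
#'   `VIP > threshold` instead of the scores.
#' @return Numeric VIP vector, or logical filter if `threshold` given.
#' @export
vip_scores <- function(model, threshold = NULL) {
  if (is.null(threshold)) model$vip else model$vip > threshold
}

#' S-line of a fitted OPLS-DA model
#'
#' Per-variable covariance (magnitude axis) and Pearson correlation
#' (color axis) between the scaled variable and the predictive score.
#' Positive values mean higher intensity in the positive class.
#'
#' @param model An `opls_model`.
#' @param centers Optional variable positions (e.g. bin centers in ppm).
#' @return Data frame with `covariance` and `correlation` (plus `ppm`
#'   when `centers` is given).
#' @export
s_line <- function(model, centers = NULL) {
  df <- data.frame(covariance = model$s_covariance,
                   correlation = model$s_correlation)
  if (!is.null(centers)) df <- cbind(ppm = centers, df)
  df
}

#' Predicted class scores for new samples
#'
#' @param object An `opls_model`.
#' @param newdata Matrix of new rows, scaled the same way as the
#'   training matrix.
#' @param ... Unused.
#' @return Data frame with predictive `score`, `y_hat` and `class`
#'   (threshold at 0).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  sc <- opls_project(list(w = object$weights, W_o = object$ortho_weights,
                          P_o = object$ortho_loadings), Xn)
  yh <- sc * object$q
  neg <- setdiff(object$classes, object$positive_class)
  data.frame(score = sc, y_hat = yh,
             class = ifelse(yh > 0, object$positive_class, neg))
}
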