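# Scaling, NIPALS PCA against an SVD oracle, OPLS-DA diagnostics, VIP
# and S-line identities.

test_that("pareto and unit-variance scaling match hand computation", {
  m <- cbind(a = c(1, 3), b = c(2, 2), d = c(0, 4))
  sm <- suppressWarnings(scale_columns(m, "pareto"))
  expect_equal(sm$center[["a"]], 2)
  expect_equal(sm$scale[["a"]], sqrt(sqrt(2)))
  expect_equal(sm$values[, "a"], c(-1, 1) / 2^0.25)
  expect_equal(sm$zero_variance, c(b = 2L))
  expect_equal(sm$values[, "b"], c(0, 0))
  expect_equal(unscale(sm), m, tolerance = 1e-10, ignore_attr = TRUE)

  su <- suppressWarnings(scale_columns(m, "uv"))
  expect_equal(sd(su$values[, "d"]), 1)
  expect_warning(scale_columns(m, "uv"), "zero-variance")
  expect_error(scale_columns(m[1, , drop = FALSE]), "2 rows")
})

test_that("NIPALS PCA matches the SVD oracle up to sign", {
  set.seed(101)
  for (trial in 1:100) {
    X <- matrix(rnorm(200), 10, 20)
    Xc <- scale(X, scale = FALSE)
    pc <- fit_pca(Xc, 2)
    sv <- svd(Xc)
    for (k in 1:2) {
      sgn <- sign(sum(pc$loadings[, k] * sv$v[, k]))
      expect_equal(pc$loadings[, k], sgn * sv$v[, k], tolerance = 1e-6)
      expect_equal(pc$scores[, k], sgn * sv$u[, k] * sv$d[k],
                   tolerance = 1e-6)
    }
    expect_equal(pc$explained_variance_fraction,
                 (sv$d^2 / sum(sv$d^2))[1:2], tolerance = 1e-8)
  }
})

test_that("PCA components are orthogonal with non-increasing variance", {
  set.seed(5)
  X <- scale(matrix(rnorm(30 * 12), 30, 12), scale = FALSE)
  pc <- fit_pca(X, 4)
  cc <- crossprod(pc$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-7)
  expect_true(all(diff(pc$explained_variance_fraction) <= 1e-10))
  expect_lte(sum(pc$explained_variance_fraction), 1 + 1e-10)
  ll <- crossprod(pc$loadings)
  expect_equal(ll, diag(4), tolerance = 1e-7, ignore_attr = TRUE)

  # rank-1 input: first component carries everything
  r1 <- tcrossprod(rnorm(8), rnorm(5))
  expect_equal(fit_pca(r1, 1)$explained_variance_fraction, 1,
               tolerance = 1e-9)
  expect_error(fit_pca(X, 40), "n_components")
})

test_that("OPLS-DA with no orthogonal component reduces to PLS1", {
  gd <- separated_groups()
  sc <- scale_columns(gd$X, "uv")
  om <- fit_oplsda(sc, gd$y, n_ortho = 0, positive_class = "B")
  y <- ifelse(gd$y == "B", 1, -1); y <- y - mean(y)
  or <- pls1_oracle(sc$values, y)
  sgn <- sign(sum(om$weights * or$w))
  expect_equal(om$weights, sgn * or$w, tolerance = 1e-8)
  expect_equal(om$scores, sgn * or$t, tolerance = 1e-8)
  expect_equal(om$q * sgn, or$q, tolerance = 1e-8)
})

test_that("OPLS-DA diagnostics behave: orthogonality, Q2 <= R2Y, bounds", {
  set.seed(9)
  for (trial in 1:5) {
    gd <- separated_groups(n_per = 8, p = 15, effect = 2, seed = trial)
    om <- fit_oplsda(scale_columns(gd$X, "uv"), gd$y, n_ortho = 1,
                     positive_class = "B")
    expect_lt(abs(sum(om$scores * om$ortho_scores[, 1])), 1e-8)
    expect_gte(om$R2Y, 0); expect_lte(om$R2Y, 1)
    expect_lte(om$Q2, om$R2Y)
    expect_gte(om$R2X, 0); expect_lte(om$R2X, 1 + 1e-10)
  }
})

test_that("well-separated groups give high cross-validated Q2", {
  gd <- separated_groups(n_per = 12, p = 40, n_inf = 10, effect = 6)
  om <- fit_oplsda(scale_columns(gd$X, "uv"), gd$y, positive_class = "B")
  expect_gt(om$Q2, 0.9)
})

test_that("Q2 is invariant to sample order given the same fold assignment", {
  gd <- separated_groups(n_per = 7, p = 12, effect = 2, seed = 13)
  sc <- scale_columns(gd$X, "uv")$values
  n <- nrow(sc)
  folds <- ((seq_len(n) - 1) %% 7) + 1
  om1 <- fit_oplsda(sc, gd$y, folds = folds, positive_class = "B")
  set.seed(2); perm <- sample(n)
  om2 <- fit_oplsda(sc[perm, ], gd$y[perm], folds = folds[perm],
                    positive_class = "B")
  expect_equal(om2$Q2, om1$Q2, tolerance = 1e-10)
})

test_that("label permutation collapses Q2", {
  gd <- separated_groups(n_per = 8, p = 20, effect = 3, seed = 77)
  sc <- scale_columns(gd$X, "uv")
  om <- fit_oplsda(sc, gd$y, positive_class = "B")
  set.seed(31)
  qs <- replicate(40, fit_oplsda(sc, sample(gd$y), positive_class = "B")$Q2)
  expect_gte(mean(qs < om$Q2), 0.95)
})

test_that("OPLS-DA input contracts are enforced", {
  gd <- separated_groups(n_per = 4, p = 6)
  expect_error(fit_oplsda(scale_columns(gd$X, "uv"),
                          rep(c("A", "B", "C"), length.out = 8)), "2 classes")
  expect_error(fit_oplsda(scale_columns(gd$X, "uv"),
                          c("A", rep("B", 7))), ">= 2 members")
})

test_that("VIP satisfies its normalization identities", {
  gd <- separated_groups()
  om <- fit_oplsda(scale_columns(gd$X, "uv"), gd$y, positive_class = "B")
  p <- ncol(gd$X)
  expect_equal(sum(om$vip^2), p, tolerance = 1e-8)
  expect_equal(mean(vip_scores(om)^2), 1, tolerance = 1e-8)
  expect_type(vip_scores(om, threshold = 1), "logical")

  # identical variables: all VIP equal 1
  set.seed(4)
  y <- rep(c("A", "B"), each = 6)
  base <- rnorm(12)
  Xeq <- matrix(rep(base + 2 * (y == "B"), 5), 12, 5)
  om_eq <- fit_oplsda(Xeq - mean(Xeq), y, n_ortho = 0, positive_class = "B")
  expect_equal(om_eq$vip, rep(1, 5), tolerance = 1e-8)

  # one variable carrying all class covariance approaches sqrt(p)
  Xone <- cbind(ifelse(y == "B", 1, -1) + rnorm(12, 0, 1e-4),
                matrix(rnorm(12 * 7, 0, 1e-4), 12, 7))
  om_one <- fit_oplsda(scale(Xone, scale = FALSE), y, n_ortho = 0,
                       positive_class = "B")
  expect_equal(om_one$vip[1], sqrt(8), tolerance = 0.01)
})

test_that("S-line covariance and correlation identify score-like variables", {
  set.seed(21)
  y <- rep(c("A", "B"), each = 10)
  sig <- ifelse(y == "B", 1.5, -1.5) + rnorm(20, 0, 0.1)
  orth <- rnorm(20)
  orth <- orth - sig * sum(orth * sig) / sum(sig^2)
  X <- cbind(v_sig = sig, v_orth = orth,
             matrix(rnorm(20 * 4, 0, 0.5), 20, 4))
  om <- fit_oplsda(scale(X, scale = FALSE), y, n_ortho = 0,
                   positive_class = "B")
  sl <- s_line(om, centers = seq_len(ncol(X)))
  expect_gt(sl$correlation[1], 0.99)
  expect_lt(abs(sl$covariance[2]), 0.05)
  expect_equal(names(sl), c("ppm", "covariance", "correlation"))
})

test_that("class prediction projects orthogonal variation out first", {
  gd <- separated_groups(n_per = 10, p = 20, effect = 5)
  sc <- scale_columns(gd$X, "uv")
  om <- fit_oplsda(sc, gd$y, n_ortho = 1, positive_class = "B")
  pred <- predict(om, sc$values)
  expect_equal(pred$class, gd$y)
  expect_gt(min(pred$score[gd$y == "B"]), max(pred$score[gd$y == "A"]))
})
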