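# Shared fixtures and small independent oracles used across test files.

# Two-spin AB system at given shifts (ppm) and coupling (Hz).
ab_system <- function(d1, d2, J) {
  spin_system("ab", c(d1, d2), c(1, 1), matrix(c(0, J, J, 0), 2))
}

# Closed-form AB quartet: line positions (ppm) and intensities for a
# two-spin system, independent of the Hamiltonian code path.
ab_quartet_oracle <- function(d1, d2, J, field) {
  dv <- (d2 - d1) * field
  C <- sqrt(dv^2 + J^2)
  m <- (d1 + d2) / 2 * field
  f <- c(m - (C + J) / 2, m - (C - J) / 2, m + (C - J) / 2, m + (C + J) / 2)
  i <- c((1 - J / C) / 2, (1 + J / C) / 2, (1 + J / C) / 2, (1 - J / C) / 2)
  list(frequency_ppm = f / field, intensity = i)
}

# Single-component PLS1 by NIPALS, written independently of the package's
# O-PLS implementation.
pls1_oracle <- function(X, y) {
  w <- crossprod(X, y)
  w <- w / sqrt(sum(w^2))
  t_vec <- X %*% w
  p_vec <- crossprod(X, t_vec) / sum(t_vec^2)
  q <- as.numeric(crossprod(y, t_vec) / sum(t_vec^2))
  list(w = as.numeric(w), t = as.numeric(t_vec), p = as.numeric(p_vec), q = q)
}

# Memoized cohort property battery so several acceptance blocks can share
# one expensive set of runs within a test session.
cohort_battery <- local({
  cache <- new.env(parent = emptyenv())
  function(n_runs = 50, base_seed = 1000) {
    key <- paste(n_runs, base_seed, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- replicate_cohort_properties(n_runs, base_seed)
    cache[[key]]
  }
})

# A small two-group dataset with a strong class effect in the first
# `n_inf` variables, for OPLS-DA behaviour tests.
separated_groups <- function(n_per = 10, p = 30, n_inf = 5, effect = 4,
                             seed = 42) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  X[y == "B", seq_len(n_inf)] <- X[y == "B", seq_len(n_inf)] + effect
  list(X = X, y = y)
}
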