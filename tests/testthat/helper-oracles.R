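# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use a different computational route than the package.

# weighted correlation by the definition, double loop, no matrix algebra
oracle_weighted_correlation <- function(X, w) {
  w <- w / sum(w)
  p <- ncol(X)
  mu <- vapply(seq_len(p), function(k) sum(w * X[, k]), numeric(1))
  C <- matrix(NA_real_, p, p)
  for (k in seq_len(p)) {
    for (l in seq_len(p)) {
      C[k, l] <- sum(w * (X[, k] - mu[k]) * (X[, l] - mu[l]))
    }
  }
  C / sqrt(outer(diag(C), diag(C)))
}

# brute-force weighted PCA: explicit correlation + dense symmetric eigensolver
# through a different builder (cov.wt) than the implementation's crossprod path
oracle_weighted_pca <- function(X, w) {
  cw <- stats::cov.wt(X, wt = w / sum(w), cor = TRUE, method = "ML")
  ee <- eigen(cw$cor, symmetric = TRUE)
  list(values = ee$values, vectors = ee$vectors)
}

# textbook Welch statistic from first principles
oracle_welch <- function(x1, x2) {
  v1 <- sum((x1 - mean(x1))^2) / (length(x1) - 1)
  v2 <- sum((x2 - mean(x2))^2) / (length(x2) - 1)
  se2 <- v1 / length(x1) + v2 / length(x2)
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x1)^2 * (length(x1) - 1)) +
                   v2^2 / (length(x2)^2 * (length(x2) - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# textbook Pearson correlation test (t with n - 2 df)
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum(scale(x) * scale(y)) / (n - 1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# a sample with exactly the requested mean and sample SD
fixture_sample <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- stats::rnorm(n)
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# compact two-group cohort for pipeline-level tests
fixture_cohort <- function(seed = 1, n_variables = 4, effects = NULL,
                           p = 31, modes = 3) {
  disc <- if (is.null(effects)) {
    data.frame(variable = integer(0), mode = integer(0), effect = numeric(0))
  } else effects
  generate_cohort(synthetic_config(
    n_subjects_case = 14, n_subjects_control = 12,
    trials_range = c(2L, 4L), n_variables = n_variables, p = p,
    modes_per_variable = modes, discriminative = disc,
    subject_sd = 0.5, trial_sd = 1, seed = seed))
}
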