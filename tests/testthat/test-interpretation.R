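test_that("Hedges' g implements the pooled-SD corrected effect size", {
  expect_equal(hedges_g(3, 1, 10, 3, 2, 12), 0)

  # rectus-femoris-force PC1 summaries of a 452-trial hop cohort
  expect_equal(round(hedges_g(-1.63, 4.45, 301, 3.31, 5.44, 151), 3),
               -1.027)

  # antisymmetry in the group order
  expect_equal(hedges_g(1, 2, 20, 3, 1, 15),
               -hedges_g(3, 1, 15, 1, 2, 20))

  expect_error(hedges_g(1, 0, 10, 2, 0, 10), "undefined")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10), "at least 2")
})

test_that("main-feature confirmation flags by the strict level", {
  set.seed(61)
  n <- 80
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  x <- rnorm(n)                               # independent of the groups
  strong <- ifelse(y == "case", 2, -2) + rnorm(n, sd = 1)
  values <- cbind(null_f = x, strong_f = strong)
  tab <- structure(list(values = values, labels = y,
                        feature_ids = colnames(values),
                        map = data.frame(feature_id = colnames(values),
                                         variable = colnames(values), pc = 1L)),
                   class = "feature_table")
  res <- main_feature_tests(tab, c("null_f", "strong_f"), alpha = 0.001)
  expect_false(res$significant[1])
  expect_true(res$significant[2])
  expect_equal(attr(res, "n_significant"), 1)

  # boundary: alpha = 1 flags everything
  res_all <- main_feature_tests(tab, c("null_f", "strong_f"), alpha = 1)
  expect_true(all(res_all$significant))

  expect_error(main_feature_tests(tab, "absent"), "not present")
})

test_that("a powered shift at cohort scale is flagged at alpha = 0.001", {
  # true standardized shift 0.8 at n = (301, 151): power > 99%
  set.seed(62)
  hits <- 0
  for (r in 1:20) {
    y <- factor(rep(c("case", "control"), c(301, 151)),
                levels = c("case", "control"))
    z <- c(rnorm(301, 0.8), rnorm(151, 0))
    hits <- hits + (welch_t(z, y)$p < 0.001)
  }
  expect_gte(hits, 19)
})

test_that("associated features obey the correlation and separation rules", {
  set.seed(63)
  # sign-vector construction on n = 96 trials: the half_f candidate has a
  # float-exact Pearson correlation of 0.5 with the main feature, probing
  # the inclusive lower bound of the moderate band
  n <- 96
  h <- function(k) rep(rep(c(1, -1), each = k), length.out = n)
  main <- h(1)
  half <- main + h(2) + h(4) + h(8)
  y <- factor(ifelse(main > 0, "case", "control"),
              levels = c("case", "control"))
  noise <- rnorm(n)
  copy <- -2 * main + rnorm(n, sd = 0.01)   # near-exact scaled negative copy
  values <- cbind(main_f = main, half_f = half, noise_f = noise,
                  copy_f = copy)
  tab <- structure(list(values = values, labels = y,
                        feature_ids = colnames(values),
                        map = data.frame(feature_id = colnames(values),
                                         variable = colnames(values), pc = 1L)),
                   class = "feature_table")
  res <- associated_features(tab, "main_f")

  expect_true(all(res$main_feature_id == "main_f"))
  expect_false("main_f" %in% res$associated_feature_id)

  # the scaled negative copy is a strong associate with rho ~ -1
  crow <- res[res$associated_feature_id == "copy_f", ]
  expect_equal(crow$rho, -1, tolerance = 1e-3)
  expect_equal(crow$strength, "strong")

  # |rho| = 0.5 exactly is included, as moderate
  hrow <- res[res$associated_feature_id == "half_f", ]
  expect_equal(nrow(hrow), 1)
  expect_identical(hrow$rho, 0.5)
  expect_equal(hrow$strength, "moderate")

  # independent noise is excluded
  expect_false("noise_f" %in% res$associated_feature_id)
})

test_that("feature interpretation produces quartile and variance curves", {
  set.seed(64)
  n <- 38; p <- 25
  curve <- sin(seq(0.15, pi - 0.15, length.out = p))  # nonzero at every phase
  amp <- rnorm(n, sd = 3)
  X <- 2 + outer(amp, curve)                  # rank-1 cohort
  labels <- factor(rep(c("case", "control"), length.out = n),
                   levels = c("case", "control"))
  w <- rep(1, n)
  fit <- fit_pca(X + matrix(rnorm(n * p, sd = 1e-3), n, p), w)
  it <- interpret_feature(X, fit, 1, labels)

  # quartile memberships partition with the ceiling rule
  expect_equal(length(it$upper_idx), ceiling(n / 4))
  expect_equal(length(it$lower_idx), ceiling(n / 4))
  expect_length(intersect(it$upper_idx, it$lower_idx), 0)

  # a single mode explains essentially all variance wherever it has amplitude
  active <- which(abs(curve) > 0.2)
  expect_true(all(it$explained_curve[active] > 0.99))
  expect_true(all(it$explained_curve >= 0 & it$explained_curve <= 1))

  # the quartile means straddle the grand mean along the mode
  mid <- colMeans(X)
  expect_true(all((it$upper_mean - mid)[active] * (it$lower_mean - mid)[active] < 0))

  # the case-nearest quartile follows the group mean score comparison
  z <- fit$Z[, 1]
  expected <- if (mean(z[labels == "case"]) > mean(z[labels == "control"]))
    "upper" else "lower"
  expect_equal(it$aclr_nearest, expected)

  expect_error(interpret_feature(X, fit, 99, labels), "out of range")
})

test_that("the explained-variance curve ignores per-column affine rescaling", {
  set.seed(65)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, p) + outer(rnorm(n, sd = 2),
                                          cos(seq(0, pi, length.out = p)))
  labels <- factor(rep(c("case", "control"), each = n / 2),
                   levels = c("case", "control"))
  w <- runif(n, 0.5, 2)
  fit <- fit_pca(X, w)
  it1 <- interpret_feature(X, fit, 1, labels)
  X2 <- sweep(sweep(X, 2, runif(p, 0.5, 3), "*"), 2, rnorm(p), "+")
  it2 <- interpret_feature(X2, fit, 1, labels)
  expect_equal(it1$explained_curve, it2$explained_curve, tolerance = 1e-10)
})

test_that("under isotropic noise the explained curve averages near 1/p", {
  set.seed(66)
  n <- 300; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  labels <- factor(rep(c("case", "control"), each = n / 2),
                   levels = c("case", "control"))
  fit <- fit_pca(X, rep(1, n))
  means <- sapply(1:3, function(j) {
    mean(interpret_feature(X, fit, j, labels)$explained_curve)
  })
  expect_true(all(abs(means - 1 / p) < 0.06))
})
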