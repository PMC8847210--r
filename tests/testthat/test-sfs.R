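two_class_table <- function(values, labels) {
  structure(list(values = values,
                 labels = factor(labels, levels = c("case", "control")),
                 feature_ids = colnames(values),
                 map = data.frame(feature_id = colnames(values),
                                  variable = colnames(values),
                                  pc = 1L, stringsAsFactors = FALSE)),
            class = "feature_table")
}

test_that("the Gaussian naive Bayes matches hand-computed posteriors", {
  train_x <- rbind(c(0, 0), c(1, 1), c(4, 5), c(5, 4), c(6, 5))
  train_y <- factor(c("case", "case", "control", "control", "control"),
                    levels = c("case", "control"))
  model <- nb_fit(train_x, train_y)
  test_x <- rbind(c(0.5, 0.5), c(5, 5), c(2.4, 2.4), c(10, -10))

  # manual Gaussian-NB arithmetic with the same floored variances
  manual <- apply(test_x, 1, function(pt) {
    ll <- sapply(c("case", "control"), function(cls) {
      log(model$priors[cls]) +
        sum(dnorm(pt, model$means[, cls], sqrt(model$vars[, cls]),
                  log = TRUE))
    })
    if (ll[1] >= ll[2]) "case" else "control"
  })
  expect_equal(as.character(nb_predict(model, test_x)), unname(manual))

  # well-separated 1-D classes train to zero error
  x1 <- matrix(c(rnorm(20, -5), rnorm(30, 5)), ncol = 1)
  y1 <- factor(rep(c("case", "control"), c(20, 30)),
               levels = c("case", "control"))
  m1 <- nb_fit(x1, y1)
  expect_equal(mean(nb_predict(m1, x1) != y1), 0)

  # with equal class-conditional distributions the larger prior wins
  set.seed(51)
  x2 <- matrix(rnorm(50), ncol = 1)
  m2 <- nb_fit(x2, y1)
  m2$means[] <- 0; m2$vars[] <- 1
  expect_true(all(nb_predict(m2, x2) == "control"))
})

test_that("naive Bayes agrees with an independent reference implementation", {
  set.seed(52)
  x <- matrix(rnorm(80 * 3), 80, 3)
  x[1:40, 1] <- x[1:40, 1] + 1.5
  y <- factor(rep(c("case", "control"), each = 40),
              levels = c("case", "control"))
  colnames(x) <- paste0("f", 1:3)
  ours <- nb_predict(nb_fit(x, y), x)
  ref <- e1071::naiveBayes(x, y)
  expect_equal(as.character(ours),
               as.character(predict(ref, x)))
})

test_that("cross-validated misclassification behaves at the extremes", {
  set.seed(53)
  n <- 400
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))

  # perfectly separable feature: rate 0 for any fold seed
  sep <- matrix(ifelse(y == "case", 5, -5) + rnorm(n, sd = 0.3), ncol = 1)
  for (s in 1:3) {
    expect_equal(cv_misclassification(sep, y, seed = s), 0)
  }

  # pure-noise feature: chance level
  noise <- matrix(rnorm(n), ncol = 1)
  rates <- sapply(1:5, function(s) cv_misclassification(noise, y, seed = s))
  expect_true(all(abs(rates - 0.5) < 0.1))

  # determinism: same seed, same fold assignment, same rate
  expect_identical(cv_misclassification(noise, y, seed = 99),
                   cv_misclassification(noise, y, seed = 99))

  # stratification needs enough trials per class
  expect_error(cv_misclassification(noise[1:12, , drop = FALSE],
                                    factor(rep(c("case", "control"),
                                               c(4, 8)),
                                           levels = c("case", "control")),
                                    folds = 10),
               "stratify")
})

test_that("a single forward pass keeps only strictly improving features", {
  set.seed(54)
  n <- 200
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  values <- cbind(perfect = ifelse(y == "case", 3, -3) + rnorm(n, sd = 0.2),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n),
                  n5 = rnorm(n))
  tab <- two_class_table(values, y)

  # the separator alone achieves rate 0; nothing can strictly improve on it
  for (s in 1:5) {
    expect_identical(sfs_once(tab, seed = s), "perfect")
  }

  # never more features than exist
  tab3 <- two_class_table(values[, 1:3], y)
  expect_lte(length(sfs_once(tab3, seed = 1)), 3)

  # labels independent of all features: selection stalls early
  noise_tab <- two_class_table(values[, 2:6], y)
  sizes <- sapply(1:10, function(s) length(sfs_once(noise_tab, seed = s)))
  expect_true(mean(sizes) <= 2.5)
})

test_that("consensus selection tallies frequencies deterministically", {
  set.seed(55)
  n <- 120
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  values <- cbind(strong = ifelse(y == "case", 3, -3) + rnorm(n, sd = 0.5),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- two_class_table(values, y)

  sel <- select_main_features(tab, iterations = 20, top = 2, seed = 7)
  expect_equal(unname(sel$frequency["strong"]), 20)
  expect_equal(sel$main_features[1], "strong")
  expect_lte(length(sel$main_features), 2)

  # frequency conservation
  expect_equal(sum(sel$frequency),
               sum(lengths(sel$per_iteration_sets)))

  # master-seed determinism
  sel2 <- select_main_features(tab, iterations = 20, top = 2, seed = 7)
  expect_identical(sel$per_iteration_sets, sel2$per_iteration_sets)
  expect_identical(sel$main_features, sel2$main_features)

  # a single iteration returns exactly that run's set
  sel1 <- select_main_features(tab, iterations = 1, seed = 3)
  expect_identical(sel1$main_features, sel1$per_iteration_sets[[1]])
})
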