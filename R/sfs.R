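#' Gaussian naive Bayes classifier for two-group score data
#'
#' Class-conditional model used inside the sequential forward selection
#' wrapper: empirical class priors, per-feature class means and variances
#' (`n - 1` denominator), independence across features. Variances are
#' floored at `1e-9` times the feature's pooled training variance so a fold
#' in which one class is (near-)constant on a feature cannot produce an
#' infinite density.
#'
#' @param x numeric `m x f` training matrix.
#' @param labels factor with levels `case`, `control`, aligned to rows.
#' @return Object of class `nb_model` with `priors`, `means`, `vars`
#'   (each `f x 2`, columns case/control).
#' @export
nb_fit <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  labels <- check_labels(labels, nrow(x))
  n1 <- sum(labels == "case"); n2 <- sum(labels == "control")
  if (n1 < 2L || n2 < 2L) {
    stop("naive Bayes training requires at least 2 trials per class")
  }
  x1 <- x[labels == "case", , drop = FALSE]
  x2 <- x[labels == "control", , drop = FALSE]
  pooled <- apply(x, 2L, stats::var)
  floor_v <- pmax(1e-9 * pooled, 1e-300)
  m <- cbind(case = colMeans(x1), control = colMeans(x2))
  v <- cbind(case = pmax(apply(x1, 2L, stats::var), floor_v),
             control = pmax(apply(x2, 2L, stats::var), floor_v))
  structure(list(priors = c(case = n1, control = n2) / (n1 + n2),
                 means = m, vars = v),
            class = "nb_model")
}

#' Predict group membership with a fitted naive Bayes model
#'
#' Argmax over classes of log prior plus summed per-feature Gaussian log
#' densities; exact posterior ties go to the case class (deterministic,
#' measure-zero for continuous scores).
#'
#' @param model a [nb_fit()] result.
#' @param newx numeric `m x f` matrix.
#' @return factor of predicted labels with levels `case`, `control`.
#' @export
nb_predict <- function(model, newx) {
  if (is.vector(newx)) newx <- matrix(newx, ncol = 1L)
  ll <- function(cls) {
    m <- model$means[, cls]; v <- model$vars[, cls]
    dc <- sweep(newx, 2L, m, "-")
    rowSums(sweep(dc^2, 2L, -2 * v, "/") -
              matrix(0.5 * log(2 * pi * v), nrow(newx), ncol(newx),
                     byrow = TRUE)) + log(model$priors[cls])
  }
  pred <- ifelse(ll("case") >= ll("control"), "case", "control")
  factor(pred, levels = c("case", "control"))
}

make_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds) {
      stop("class '", cls, "' has ", length(idx),
           " trials, fewer than the ", folds, " folds; cannot stratify")
    }
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

#' Cross-validated misclassification rate of a naive Bayes classifier
#'
#' Stratified k-fold cross-validation: fold labels are assigned at random
#' within each class, the model is trained on the remaining folds and the
#' pooled fraction of misclassified held-out trials is returned (pooling,
#' rather than averaging per-fold rates, is invariant to unequal fold
#' sizes).
#'
#' @param values numeric `n x f` matrix of feature scores.
#' @param labels factor with levels `case`, `control`.
#' @param folds number of folds (default 10).
#' @param seed optional seed fixing the fold assignment.
#' @return Misclassified fraction in `[0, 1]`.
#' @export
cv_misclassification <- function(values, labels, folds = 10L, seed = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  labels <- check_labels(labels, nrow(values))
  if (!is.null(seed)) set.seed(seed)
  assign <- make_folds(labels, folds)
  wrong <- 0L
  for (f in seq_len(folds)) {
    test <- assign == f
    model <- nb_fit(values[!test, , drop = FALSE], labels[!test])
    pred <- nb_predict(model, values[test, , drop = FALSE])
    wrong <- wrong + sum(pred != labels[test])
  }
  wrong / nrow(values)
}

# Per-fold, per-class, per-feature Gaussian log densities for every row
# evaluated under the model trained on the complementary folds. Because the
# naive Bayes log posterior is additive over features, the CV error of any
# feature subset is recoverable by summing slices, which is what makes the
# greedy search cheap.
nb_fold_cache <- function(values, labels, assign) {
  n <- nrow(values); f <- ncol(values)
  D1 <- matrix(0, n, f); D2 <- matrix(0, n, f)
  b1 <- numeric(n); b2 <- numeric(n)
  is_case <- labels == "case"
  for (fold in sort(unique(assign))) {
    test <- assign == fold
    tr <- !test
    x1 <- values[tr & is_case, , drop = FALSE]
    x2 <- values[tr & !is_case, , drop = FALSE]
    n1 <- nrow(x1); n2 <- nrow(x2)
    if (n1 < 2L || n2 < 2L) stop("training fold with fewer than 2 trials in a class")
    pooled <- colSums(sweep(values[tr, , drop = FALSE], 2L,
                            colMeans(values[tr, , drop = FALSE]), "-")^2) /
              (n1 + n2 - 1L)
    floor_v <- pmax(1e-9 * pooled, 1e-300)
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    v1 <- pmax(colSums(sweep(x1, 2L, m1, "-")^2) / (n1 - 1L), floor_v)
    v2 <- pmax(colSums(sweep(x2, 2L, m2, "-")^2) / (n2 - 1L), floor_v)
    xt <- values[test, , drop = FALSE]
    D1[test, ] <- -0.5 * sweep(sweep(xt, 2L, m1, "-")^2, 2L, v1, "/") -
      matrix(0.5 * log(2 * pi * v1), nrow(xt), f, byrow = TRUE)
    D2[test, ] <- -0.5 * sweep(sweep(xt, 2L, m2, "-")^2, 2L, v2, "/") -
      matrix(0.5 * log(2 * pi * v2), nrow(xt), f, byrow = TRUE)
    b1[test] <- log(n1 / (n1 + n2))
    b2[test] <- log(n2 / (n1 + n2))
  }
  list(D1 = D1, D2 = D2, b1 = b1, b2 = b2, is_case = is_case)
}

#' One run of sequential forward feature selection
#'
#' Greedy wrapper around the cross-validated naive Bayes error: starting
#' from the empty set, every remaining feature is evaluated together with
#' the current set, the best is added only if it *strictly* lowers the
#' pooled CV misclassification rate, and selection stops otherwise or when
#' `max_features` is reached. One stratified fold assignment is drawn per
#' run and shared by all candidate evaluations; equal candidate rates are
#' broken toward the earliest feature in table order.
#'
#' @param table a [feature_table] (or `wi_filter`d table).
#' @param max_features largest admissible set size (default 10).
#' @param folds CV folds (default 10).
#' @param seed optional seed fixing the fold assignment.
#' @return Character vector of selected feature ids, in selection order.
#' @export
sfs_once <- function(table, max_features = 10L, folds = 10L, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(seed)) set.seed(seed)
  labels <- check_labels(table$labels, nrow(table$values))
  assign <- make_folds(labels, folds)
  cache <- nb_fold_cache(table$values, labels, assign)
  n <- nrow(table$values)
  L1 <- cache$b1; L2 <- cache$b2
  cur_err <- mean((L1 >= L2) != cache$is_case)
  rem <- seq_len(ncol(table$values))
  sel <- integer(0)
  while (length(sel) < max_features && length(rem) > 0L) {
    E1 <- L1 + cache$D1[, rem, drop = FALSE]
    E2 <- L2 + cache$D2[, rem, drop = FALSE]
    errs <- colMeans((E1 >= E2) != cache$is_case)
    best <- which.min(errs)            # first minimum = earliest table order
    if (errs[best] < cur_err) {
      j <- rem[best]
      sel <- c(sel, j)
      L1 <- L1 + cache$D1[, j]
      L2 <- L2 + cache$D2[, j]
      cur_err <- errs[best]
      rem <- rem[-best]
    } else break
  }
  table$feature_ids[sel]
}

#' Consensus main features over repeated sequential forward selections
#'
#' Each selection run randomizes its cross-validation folds, so repeated
#' runs pick different sets; the features most frequently chosen across
#' runs form the consensus. The `top` most frequent (default 10) are the
#' *main features*. Frequency ties at the cut are broken by earlier mean
#' within-run selection position, then lexicographic feature id; features
#' never selected are excluded even if fewer than `top` remain.
#'
#' @param table a [feature_table].
#' @param iterations number of selection runs (default 1000).
#' @param max_features per-run cap on set size (default 10).
#' @param top number of consensus features to keep (default 10).
#' @param folds CV folds per run (default 10).
#' @param seed master seed; per-run seeds are drawn from it.
#' @return Object of class `sfs_selection`: list with `iterations`,
#'   `per_iteration_sets`, `frequency` (named count vector over all table
#'   features), `main_features`, `seeds`, `tie_broken` (logical: whether the
#'   rank-`top` cut involved a frequency tie).
#' @export
select_main_features <- function(table, iterations = 1000L,
                                 max_features = 10L, top = 10L,
                                 folds = 10L, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(2147483646L, iterations)
  sets <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    sets[[i]] <- sfs_once(table, max_features = max_features,
                          folds = folds, seed = run_seeds[i])
  }
  ids <- table$feature_ids
  freq <- stats::setNames(integer(length(ids)), ids)
  pos_sum <- stats::setNames(numeric(length(ids)), ids)
  for (s in sets) {
    if (length(s)) {
      freq[s] <- freq[s] + 1L
      pos_sum[s] <- pos_sum[s] + seq_along(s)
    }
  }
  mean_pos <- ifelse(freq > 0, pos_sum / pmax(freq, 1L), Inf)
  cand <- ids[freq > 0L]
  ord <- order(-freq[cand], mean_pos[cand], cand)
  main <- cand[ord][seq_len(min(top, length(cand)))]
  tie_broken <- FALSE
  if (length(cand) > top) {
    cut_freq <- freq[cand[ord][top]]
    tie_broken <- sum(freq[cand] == cut_freq) >
      sum(freq[cand[ord][seq_len(top)]] == cut_freq)
  }
  structure(list(iterations = iterations,
                 per_iteration_sets = sets,
                 frequency = freq,
                 main_features = main,
                 seeds = run_seeds,
                 tie_broken = tie_broken),
            class = "sfs_selection")
}

#' @export
print.sfs_selection <- function(x, ...) {
  cat("sequential forward selection consensus over", x$iterations,
      "runs\n  main features:",
      paste(x$main_features, collapse = ", "), "\n")
  if (x$tie_broken) cat("  note: frequency tie at the cut was broken by",
                        "mean selection position / feature id\n")
  invisible(x)
}
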