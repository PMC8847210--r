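#' Pool retained principal component scores into one feature table
#'
#' Concatenates, variable by variable in the order of the cohort and rank by
#' rank within a variable, the score columns that parallel analysis retained.
#' Feature identifiers are `<variable>.PC<rank>`.
#'
#' @param cohort a [waveform_cohort()].
#' @param pcas named list of [fit_pca()] results, one per cohort variable.
#' @param pa_results named list of [retain_components()] results aligned to
#'   `pcas`.
#' @return Object of class `feature_table`: list with `values` (`n x f`
#'   score matrix, columns named by feature id), `labels` (group factor
#'   aligned to cohort rows), `feature_ids`, and `map` (data.frame
#'   variable / pc per feature).
#' @export
assemble_feature_table <- function(cohort, pcas, pa_results) {
  stopifnot(inherits(cohort, "waveform_cohort"))
  vars <- names(cohort$variables)
  cols <- list(); ids <- character(0)
  map_var <- character(0); map_pc <- integer(0)
  for (v in vars) {
    pca <- pcas[[v]]; pa <- pa_results[[v]]
    if (is.null(pca) || is.null(pa)) {
      stop("missing PCA or parallel-analysis result for variable '", v, "'")
    }
    if (nrow(pca$Z) != cohort$n) {
      stop("PCA of '", v, "' has ", nrow(pca$Z),
           " score rows; cohort has ", cohort$n, " trials")
    }
    k <- pa$retained_k
    if (k > 0L) {
      cols[[length(cols) + 1L]] <- pca$Z[, seq_len(k), drop = FALSE]
      ids <- c(ids, paste0(v, ".PC", seq_len(k)))
      map_var <- c(map_var, rep(v, k)); map_pc <- c(map_pc, seq_len(k))
    }
  }
  if (length(ids) == 0L) {
    stop("no principal components were retained for any variable; ",
         "the feature table is empty")
  }
  values <- do.call(cbind, cols)
  colnames(values) <- ids
  structure(list(values = values,
                 labels = cohort$trial_meta$group,
                 feature_ids = ids,
                 map = data.frame(feature_id = ids, variable = map_var,
                                  pc = map_pc, stringsAsFactors = FALSE)),
            class = "feature_table")
}

feature_table_subset <- function(table, keep_ids) {
  idx <- match(keep_ids, table$feature_ids)
  structure(list(values = table$values[, idx, drop = FALSE],
                 labels = table$labels,
                 feature_ids = keep_ids,
                 map = table$map[idx, , drop = FALSE]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "trials x", ncol(x$values),
      "principal-component features\n")
  invisible(x)
}

#' Welch two-sample comparison of one feature between case and control
#'
#' Unequal-variance t-test of the case-vs-control difference in mean score,
#' with sample standard deviations (`n - 1` denominator),
#' Welch--Satterthwaite degrees of freedom, a two-sided p-value, and the
#' Hedges' g standardized effect size. The statistic is oriented case minus
#' control.
#'
#' @param scores numeric vector of per-trial feature values.
#' @param labels factor with levels `case`, `control` aligned to `scores`.
#' @param feature_id optional identifier carried into the result.
#' @return One-row data.frame: `feature_id`, `mean_case`, `sd_case`,
#'   `n_case`, `mean_control`, `sd_control`, `n_control`, `t`, `df`, `p`,
#'   `g`.
#' @export
welch_t <- function(scores, labels, feature_id = NA_character_) {
  labels <- check_labels(labels, length(scores))
  x1 <- scores[labels == "case"]
  x2 <- scores[labels == "control"]
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("both groups need at least 2 trials for a Welch comparison")
  }
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  if (s1 == 0 && s2 == 0) {
    stop("both groups have zero variance; the comparison is degenerate")
  }
  tt <- stats::t.test(x1, x2, var.equal = FALSE)
  data.frame(feature_id = feature_id,
             mean_case = mean(x1), sd_case = s1, n_case = length(x1),
             mean_control = mean(x2), sd_control = s2,
             n_control = length(x2),
             t = unname(tt$statistic),
             df = unname(tt$parameter),
             p = tt$p.value,
             g = hedges_g(mean(x1), s1, length(x1),
                          mean(x2), s2, length(x2)),
             stringsAsFactors = FALSE)
}

check_labels <- function(labels, n) {
  labels <- factor(as.character(labels), levels = c("case", "control"))
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must be 'case'/'control' and aligned to the scores")
  }
  labels
}

#' Welch comparisons for every column of a feature table
#'
#' @param table a [assemble_feature_table()] result.
#' @return data.frame with one [welch_t()] row per feature.
#' @export
compare_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  out <- do.call(rbind, lapply(seq_along(table$feature_ids), function(j) {
    welch_t(table$values[, j], table$labels, table$feature_ids[j])
  }))
  rownames(out) <- NULL
  out
}

#' Weiss-Indurkhya independent feature screen
#'
#' Univariate screening of principal component features: a feature survives
#' when the magnitude of its Welch t statistic reaches `threshold`
#' (inclusive; the default 2.0 corresponds to a two-sided tail probability
#' of about 0.046 at the cohort-scale degrees of freedom). The absolute
#' value is used because principal component score signs follow an
#' arbitrary (if fixed) eigenvector sign convention.
#'
#' @param table a [assemble_feature_table()] result.
#' @param threshold retention cutoff on `|t|` (default 2.0).
#' @return Object of class `wi_filter`: list with `table` (the retained
#'   [feature_table]), `comparisons` (all input features with a `retained`
#'   flag), `n_input`, `n_retained`, `threshold`.
#' @export
wi_filter <- function(table, threshold = 2.0) {
  comp <- compare_features(table)
  comp$retained <- abs(comp$t) >= threshold
  kept <- comp$feature_id[comp$retained]
  structure(list(table = if (length(kept)) feature_table_subset(table, kept)
                         else NULL,
                 comparisons = comp,
                 n_input = nrow(comp),
                 n_retained = length(kept),
                 threshold = threshold),
            class = "wi_filter")
}

#' @export
print.wi_filter <- function(x, ...) {
  cat("Weiss-Indurkhya screen (|t| >= ", x$threshold, "): ", x$n_input,
      " -> ", x$n_retained, " features\n", sep = "")
  invisible(x)
}

#' Two-sided tail probability of the screening cutoff
#'
#' The significance level implied by retaining `|t| >= threshold` under a
#' central t distribution: `2 * P(T_df < -threshold)`. At the pooled
#' two-group degrees of freedom of a 452-trial cohort (450) the default
#' cutoff 2.0 corresponds to about 0.046.
#'
#' @param threshold the screen's cutoff on `|t|`.
#' @param df degrees of freedom.
#' @return The two-sided tail probability.
#' @export
wi_screening_level <- function(threshold = 2.0, df) {
  2 * stats::pt(-abs(threshold), df = df)
}
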