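#' Hedges' g standardized mean difference
#'
#' Pooled-standard-deviation effect size with the small-sample bias
#' correction: `d = (m1 - m2) / s_pooled` where
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, and
#' `g = d * J` with `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param m1,s1,n1 mean, sample SD and size of the first (case) group.
#' @param m2,s2,n2 mean, sample SD and size of the second (control) group.
#' @return Hedges' g (signed, first group minus second).
#' @examples
#' hedges_g(5.52, 17.32, 301, -12.06, 20.25, 151)  # ~0.957 (knee adduction
#' # moment PC1 from a 452-trial hop-landing cohort)
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("Hedges' g needs at least 2 per group")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be nonnegative")
  if (s1 == 0 && s2 == 0) {
    stop("both group variances are zero; the effect size is undefined")
  }
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  d * (1 - 3 / (4 * (n1 + n2) - 9))
}

#' Confirmatory Welch tests of the main features
#'
#' Re-tests each consensus main feature at a tight significance level
#' (default `alpha = 0.001`; the features already passed the `|t| >= 2`
#' screen, so the confirmatory level is deliberately stricter) and reports
#' the group summaries, Welch statistic, p-value and Hedges' g.
#'
#' @param table a [feature_table] containing the main features.
#' @param main character vector of main feature ids.
#' @param alpha confirmatory significance level (default 0.001).
#' @return data.frame: one [welch_t()] row per main feature plus a
#'   `significant` flag (`p < alpha`); attribute `n_significant`.
#' @export
main_feature_tests <- function(table, main, alpha = 0.001) {
  stopifnot(inherits(table, "feature_table"))
  if (!all(main %in% table$feature_ids)) {
    stop("main feature(s) not present in the table: ",
         paste(setdiff(main, table$feature_ids), collapse = ", "))
  }
  out <- do.call(rbind, lapply(main, function(id) {
    welch_t(table$values[, match(id, table$feature_ids)], table$labels, id)
  }))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "alpha") <- alpha
  out
}

#' Associated features: retained components correlated with a main feature
#'
#' Searches the retained, non-main principal components for features whose
#' score columns correlate at least moderately with a main feature's scores
#' (`0.5 <= |rho| < 0.7` moderate, `|rho| >= 0.7` strong; Pearson, with a
#' two-sided n-2-df correlation test at `alpha_corr`) and that themselves
#' separate the groups at `|t| >= t_threshold`. Such features carry
#' group-discriminating information statistically entangled with the main
#' feature rather than independent of it.
#'
#' @param table a [feature_table] holding the candidate pool and the main
#'   features (typically the full PA-retained table).
#' @param main character vector of main feature ids.
#' @param alpha_corr significance level for the correlation test
#'   (default 0.05).
#' @param t_threshold group-separation requirement on the candidate's Welch
#'   statistic (default 2.0).
#' @param alpha_strict level for the additional strict-significance flag
#'   (default 0.001).
#' @return data.frame with one row per (main feature, associated feature)
#'   pair: `main_feature_id`, `associated_feature_id`, `rho`, `rho_p`,
#'   `strength`, the associated feature's group summaries / `t` / `p` / `g`,
#'   and `significant_strict`. Zero rows if nothing qualifies.
#' @export
associated_features <- function(table, main, alpha_corr = 0.05,
                                t_threshold = 2.0, alpha_strict = 0.001) {
  stopifnot(inherits(table, "feature_table"))
  pool <- setdiff(table$feature_ids, main)
  rows <- list()
  for (m in main) {
    zm <- table$values[, match(m, table$feature_ids)]
    for (cand in pool) {
      zc <- table$values[, match(cand, table$feature_ids)]
      ct <- stats::cor.test(zm, zc, method = "pearson")
      rho <- unname(ct$estimate)
      if (is.na(rho) || abs(rho) < 0.5 || ct$p.value >= alpha_corr) next
      comp <- welch_t(zc, table$labels, cand)
      if (abs(comp$t) < t_threshold) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(main_feature_id = m,
                   associated_feature_id = cand,
                   rho = rho,
                   rho_p = ct$p.value,
                   strength = if (abs(rho) >= 0.7) "strong" else "moderate",
                   stringsAsFactors = FALSE),
        comp[, setdiff(names(comp), "feature_id")])
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(main_feature_id = character(0),
                      associated_feature_id = character(0),
                      rho = numeric(0), rho_p = numeric(0),
                      strength = character(0),
                      mean_case = numeric(0), sd_case = numeric(0),
                      n_case = integer(0), mean_control = numeric(0),
                      sd_control = numeric(0), n_control = integer(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      g = numeric(0),
                      significant_strict = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$significant_strict <- out$p < alpha_strict
  rownames(out) <- NULL
  out
}

#' Waveform-level interpretation artifacts for one principal component
#'
#' Builds the three curve families used to read a principal component as a
#' movement pattern: (i) mean and SD waveforms of the pooled trials in the
#' upper (score >= 75th percentile) and lower (score <= 25th percentile)
#' score quartiles; (ii) the component's coefficient curve (eigenvector);
#' (iii) the explained-variance curve, the squared trial-weighted
#' correlation between each phase sample of the original data and the score
#' column, showing where along the phase the component acts. Also reports
#' which quartile the case group's mean score lies nearer to.
#'
#' @param X the variable's `n x p` waveform matrix (original units).
#' @param pca the variable's [fit_pca()] result.
#' @param j principal component rank.
#' @param labels group factor aligned to rows of `X`.
#' @return Object of class `feature_interpretation`: list with `variable`,
#'   `pc`, `upper_mean`, `upper_sd`, `lower_mean`, `lower_sd` (length-p
#'   curves), `coefficient_curve`, `explained_curve`, `aclr_nearest`
#'   (`"upper"` or `"lower"`), `upper_idx`, `lower_idx`.
#' @export
interpret_feature <- function(X, pca, j, labels) {
  stopifnot(inherits(pca, "weighted_pca"))
  if (j < 1L || j > ncol(pca$Z)) {
    stop("component rank ", j, " is out of range 1..", ncol(pca$Z))
  }
  labels <- check_labels(labels, nrow(X))
  z <- pca$Z[, j]
  qs <- stats::quantile(z, probs = c(0.25, 0.75), names = FALSE, type = 7)
  lower <- which(z <= qs[1L])
  upper <- which(z >= qs[2L])
  curve_stats <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    list(mean = colMeans(Xi), sd = apply(Xi, 2L, stats::sd))
  }
  up <- curve_stats(upper); lo <- curve_stats(lower)
  w <- pca$weights
  explained <- vapply(seq_len(ncol(X)), function(k) {
    weighted_correlation(cbind(X[, k], z), w)[1L, 2L]^2
  }, numeric(1))
  aclr_nearest <- if (mean(z[labels == "case"]) > mean(z[labels == "control"]))
    "upper" else "lower"
  structure(list(variable = pca$variable,
                 pc = as.integer(j),
                 feature_id = paste0(pca$variable, ".PC", j),
                 upper_mean = up$mean, upper_sd = up$sd,
                 lower_mean = lo$mean, lower_sd = lo$sd,
                 coefficient_curve = pca$U[, j],
                 explained_curve = explained,
                 aclr_nearest = aclr_nearest,
                 upper_idx = upper, lower_idx = lower),
            class = "feature_interpretation")
}

#' Three-panel interpretation plot for one principal component
#'
#' Upper/lower-quartile mean waveforms with 1-SD envelopes, plus the
#' coefficient and explained-variance curves on a secondary panel.
#'
#' @param x a [interpret_feature()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.feature_interpretation <- function(x, ...) {
  p <- length(x$upper_mean)
  phase <- seq(0, 100, length.out = p)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(x$upper_mean + x$upper_sd, x$upper_mean - x$upper_sd,
                x$lower_mean + x$lower_sd, x$lower_mean - x$lower_sd)
  graphics::plot(phase, x$upper_mean, type = "l", col = "blue", lwd = 2,
                 ylim = ylim, xlab = "phase (%)", ylab = "waveform",
                 main = x$feature_id, ...)
  graphics::polygon(c(phase, rev(phase)),
                    c(x$upper_mean + x$upper_sd,
                      rev(x$upper_mean - x$upper_sd)),
                    col = grDevices::adjustcolor("blue", 0.15), border = NA)
  graphics::lines(phase, x$lower_mean, col = "red", lty = 2, lwd = 2)
  graphics::polygon(c(phase, rev(phase)),
                    c(x$lower_mean + x$lower_sd,
                      rev(x$lower_mean - x$lower_sd)),
                    col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::legend("topleft", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c("blue", "red"),
                   legend = c("upper quartile", "lower quartile"))
  graphics::plot(phase, x$coefficient_curve, type = "l", lwd = 2,
                 xlab = "phase (%)", ylab = "PC coefficient")
  graphics::par(new = TRUE)
  graphics::plot(phase, x$explained_curve, type = "l", lty = 2, axes = FALSE,
                 xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("explained variance", side = 4, line = -1.2, cex = 0.8)
  invisible(x)
}
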