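#' Horn's parallel-analysis eigenvalue thresholds
#'
#' Draws `n_rep` random `n x p` matrices of independent standard normal
#' entries, takes the eigenvalues of each matrix's `p x p` column
#' correlation matrix, and returns, rank by rank, the requested percentile
#' of the random eigenvalues. Observed components whose eigenvalues exceed
#' these thresholds carry more variance than size-matched noise and are
#' retained. Percentiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7). Thresholds depend only on `(n, p)`, so one
#' table is shared by every variable of a cohort.
#'
#' @param n number of trials (rows) of the observed data.
#' @param p number of phase samples (columns).
#' @param n_rep number of random replicates (1000 by default; larger
#'   improves threshold accuracy).
#' @param percentile percentile of the random eigenvalue distribution used
#'   as the retention threshold, in (0, 100); default 95.
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @return Object of class `pa_thresholds`: list with `thresholds`
#'   (length `p`, one per eigenvalue rank), `n`, `p`, `n_rep`, `percentile`,
#'   `seed`.
#' @export
pa_thresholds <- function(n, p, n_rep = 1000L, percentile = 95, seed = NULL) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100")
  }
  if (n_rep < 1L) stop("n_rep must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (p == 1L) {
    thr <- 1
  } else {
    ev <- matrix(NA_real_, nrow = n_rep, ncol = p)
    for (r in seq_len(n_rep)) {
      M <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
      ev[r, ] <- sort(eigen(stats::cor(M), symmetric = TRUE,
                            only.values = TRUE)$values,
                      decreasing = TRUE)
    }
    thr <- apply(ev, 2L, stats::quantile, probs = percentile / 100,
                 names = FALSE, type = 7)
  }
  structure(list(thresholds = thr, n = n, p = p, n_rep = n_rep,
                 percentile = percentile, seed = seed),
            class = "pa_thresholds")
}

#' Retain leading components whose eigenvalues beat the random thresholds
#'
#' Applies the contiguous-prefix rule: the retained count `k` is the largest
#' rank such that every eigenvalue up to `k` strictly exceeds its rank-wise
#' threshold. A component is never kept above a dropped one.
#'
#' @param eigenvalues nonincreasing eigenvalue sequence of the observed
#'   weighted correlation matrix.
#' @param thresholds a [pa_thresholds()] object or a numeric vector of the
#'   same length as `eigenvalues`.
#' @param variable optional label carried into the result.
#' @return Object of class `pa_result`: list with `variable`, `retained_k`,
#'   `retained_indices` (`1..k`, empty if `k = 0`), `eigenvalues`,
#'   `thresholds`.
#' @export
retain_components <- function(eigenvalues, thresholds, variable = NA_character_) {
  thr <- if (inherits(thresholds, "pa_thresholds")) thresholds$thresholds
         else thresholds
  if (length(eigenvalues) != length(thr)) {
    stop("eigenvalues (", length(eigenvalues), ") and thresholds (",
         length(thr), ") differ in length")
  }
  if (any(diff(eigenvalues) > 1e-8 * max(1, abs(eigenvalues[1L])))) {
    stop("eigenvalues must be nonincreasing")
  }
  above <- eigenvalues > thr
  k <- if (above[1L]) which.min(c(above, FALSE)) - 1L else 0L
  structure(list(variable = variable,
                 retained_k = as.integer(k),
                 retained_indices = seq_len(k),
                 eigenvalues = eigenvalues,
                 thresholds = thr),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat("parallel analysis", if (!is.na(x$variable)) paste0("(", x$variable, ")"),
      ": retained", x$retained_k, "of", length(x$eigenvalues),
      "components\n")
  invisible(x)
}
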