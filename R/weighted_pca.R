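#' Trial-weighted correlation matrix of a waveform matrix
#'
#' Correlation between phase columns with per-trial (row) weights, so that
#' subjects contributing many trials do not dominate the estimate. With
#' normalized weights `w` (summing to 1) the weighted column means are
#' `mu_k = sum_i w_i x_ik`, the weighted covariances
#' `c_kl = sum_i w_i (x_ik - mu_k)(x_il - mu_l)` (population-style
#' normalization: the divisor is `sum(w) = 1`, no degrees-of-freedom
#' correction), and `R_kl = c_kl / sqrt(c_kk c_ll)`.
#'
#' @param X numeric `n x p` matrix (rows = trials, columns = phase samples).
#' @param w per-row weights: a [compute_trial_weights()] object or a numeric
#'   vector of length `n` (normalized internally).
#' @return Symmetric `p x p` correlation matrix with unit diagonal.
#' @export
weighted_correlation <- function(X, w) {
  w <- normalize_weights(w, nrow(X))
  mu <- as.vector(crossprod(w, X))
  Xc <- sweep(X, 2L, mu, "-")
  C <- crossprod(Xc, w * Xc)
  v <- diag(C)
  if (any(v <= max(v) * 1e-14) || any(v == 0)) {
    bad <- which(v <= max(v, 1e-300) * 1e-14 | v == 0)
    stop("column(s) ", paste(bad, collapse = ", "),
         " have zero weighted variance; the variable is degenerate")
  }
  s <- sqrt(v)
  R <- C / tcrossprod(s)
  diag(R) <- 1
  (R + t(R)) / 2
}

normalize_weights <- function(w, n) {
  if (inherits(w, "trial_weights")) w <- w$w
  if (!is.numeric(w) || length(w) != n) {
    stop("weights must be a trial_weights object or a numeric vector of ",
         "length nrow(X)")
  }
  if (any(w <= 0)) stop("all trial weights must be positive")
  w / sum(w)
}

#' Weighted-correlation principal component analysis of one variable
#'
#' Eigen-decomposes the trial-weighted correlation matrix of `X` and scores
#' every trial on every component. Columns of `X` are standardized by their
#' weighted mean and weighted standard deviation before projection
#' (`Z = X_std U`), which is what makes the score columns mutually
#' uncorrelated under the trial weights. Each eigenvector is sign-fixed so
#' that its largest-magnitude coefficient is positive, removing the
#' arbitrary sign of eigenvectors.
#'
#' @inheritParams weighted_correlation
#' @param variable optional label naming the biomechanical variable.
#' @return Object of class `weighted_pca`: list with `variable`, `U`
#'   (`p x p` eigenvector matrix, columns ordered by decreasing eigenvalue),
#'   `eigenvalues` (nonincreasing, sum `p`), `Z` (`n x p` score matrix),
#'   `explained_fraction`, `weighted_means`, `weighted_sds`, `weights`.
#' @export
fit_pca <- function(X, w, variable = "X") {
  w <- normalize_weights(w, nrow(X))
  R <- weighted_correlation(X, w)
  ee <- eigen(R, symmetric = TRUE)
  ord <- order(ee$values, decreasing = TRUE)   # stable re-sort
  lambda <- pmax(ee$values[ord], 0)
  U <- ee$vectors[, ord, drop = FALSE]
  # sign convention: largest-|coefficient| entry of each eigenvector positive
  for (j in seq_len(ncol(U))) {
    k <- which.max(abs(U[, j]))
    if (U[k, j] < 0) U[, j] <- -U[, j]
  }
  mu <- as.vector(crossprod(w, X))
  Xc <- sweep(X, 2L, mu, "-")
  sds <- sqrt(as.vector(crossprod(w, Xc^2)))
  Xs <- sweep(Xc, 2L, sds, "/")
  Z <- Xs %*% U
  colnames(Z) <- colnames(U) <- paste0("PC", seq_len(ncol(U)))
  structure(list(variable = variable,
                 U = U,
                 eigenvalues = lambda,
                 Z = Z,
                 explained_fraction = lambda / sum(lambda),
                 weighted_means = mu,
                 weighted_sds = sds,
                 weights = w),
            class = "weighted_pca")
}

#' @export
print.weighted_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("weighted_pca of", x$variable, "(", nrow(x$Z), "trials x",
      ncol(x$Z), "phase points )\n  leading explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained_fraction[seq_len(k)]),
             collapse = " "), "\n")
  invisible(x)
}

#' Score new trials on a fitted weighted PCA basis
#'
#' Standardizes `X_new` with the stored weighted column means/SDs of the fit
#' and projects onto the eigenvector basis; applied to the training matrix
#' it reproduces the stored scores exactly.
#'
#' @param pca a [fit_pca()] result.
#' @param X_new numeric `m x p` matrix on the same phase grid.
#' @return `m x p` score matrix.
#' @export
project_pca <- function(pca, X_new) {
  stopifnot(inherits(pca, "weighted_pca"))
  if (is.vector(X_new)) X_new <- matrix(X_new, nrow = 1L)
  if (ncol(X_new) != nrow(pca$U)) {
    stop("X_new has ", ncol(X_new), " columns; the fitted basis expects ",
         nrow(pca$U))
  }
  Xs <- sweep(sweep(X_new, 2L, pca$weighted_means, "-"),
              2L, pca$weighted_sds, "/")
  Z <- Xs %*% pca$U
  colnames(Z) <- colnames(pca$U)
  Z
}
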