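#' Heuristic RBF bandwidth: mean pairwise distance
#'
#' Mean Euclidean distance over all unordered row pairs of the aggregated
#' sample (exact up to `max_rows` rows; a seeded subsample above that).
#'
#' @param X numeric matrix (standardized pooled rows of both datasets).
#' @param max_rows exact computation cutoff (default 2000).
#' @param seed subsample seed used above the cutoff.
#' @return positive bandwidth; errors if all rows are identical.
#' @export
heuristic_sigma <- function(X, max_rows = 2000L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  if (nrow(X) > max_rows) {
    idx <- with_local_seed(seed, sample.int(nrow(X), max_rows))
    X <- X[idx, , drop = FALSE]
  }
  s <- mean(stats::dist(X))
  if (!is.finite(s) || s <= 0) {
    stop("degenerate bandwidth: all rows are identical")
  }
  s
}

#' Weighted RBF kernel matrix
#'
#' `k(x, y) = exp(-sum_j w_f[j] * (x_j - y_j)^2 / (2 sigma^2))`: feature
#' weights scale each coordinate's squared difference, so a zero-weight
#' feature cannot move the kernel.
#'
#' @param X,Y numeric matrices with aligned columns.
#' @param w_f simplex feature weights.
#' @param sigma positive bandwidth.
#' @return `nrow(X)` by `nrow(Y)` kernel matrix.
#' @export
weighted_rbf_kernel <- function(X, Y, w_f, sigma) {
  stopifnot(sigma > 0, ncol(X) == ncol(Y), length(w_f) == ncol(X))
  sq <- sqrt(as.numeric(w_f))
  Xs <- sweep(X, 2L, sq, "*")
  Ys <- sweep(Y, 2L, sq, "*")
  an <- rowSums(Xs^2); bn <- rowSums(Ys^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(Xs, Ys)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Sample- and feature-weighted maximum mean discrepancy
#'
#' Empirical MMD between two weighted samples under the weighted RBF
#' kernel. Sample weights are normalized to sum 1 inside, so the statistic
#' is a discrepancy between weighted empirical measures: binary subsampling
#' weights become `1/n_active`, and rescaling one side's weights by a
#' constant changes nothing. A tiny negative radicand (within -1e-12) from
#' floating point is clamped to zero.
#'
#' @param X,Y numeric matrices with aligned columns.
#' @param w_X,w_Y nonnegative sample weights (default uniform); each must
#'   have a positive sum.
#' @param w_f simplex feature weights (default uniform).
#' @param sigma positive bandwidth; `"heuristic"` uses the mean pairwise
#'   distance over the pooled rows of X and Y.
#' @return nonnegative MMD estimate.
#' @export
weighted_mmd <- function(X, Y, w_X = NULL, w_Y = NULL, w_f = NULL,
                         sigma = "heuristic") {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y))
  if (is.null(w_X)) w_X <- rep(1, nrow(X))
  if (is.null(w_Y)) w_Y <- rep(1, nrow(Y))
  stopifnot(length(w_X) == nrow(X), length(w_Y) == nrow(Y),
            all(w_X >= 0), all(w_Y >= 0))
  if (sum(w_X) <= 0 || sum(w_Y) <= 0) stop("sample weights sum to zero")
  if (is.null(w_f)) w_f <- rep(1 / ncol(X), ncol(X))
  if (identical(sigma, "heuristic")) sigma <- heuristic_sigma(rbind(X, Y))
  a <- w_X / sum(w_X)
  b <- w_Y / sum(w_Y)
  Kxx <- weighted_rbf_kernel(X, X, w_f, sigma)
  Kyy <- weighted_rbf_kernel(Y, Y, w_f, sigma)
  Kxy <- weighted_rbf_kernel(X, Y, w_f, sigma)
  m2 <- drop(t(a) %*% Kxx %*% a) - 2 * drop(t(a) %*% Kxy %*% b) +
    drop(t(b) %*% Kyy %*% b)
  if (m2 < 0) {
    if (m2 < -1e-12) warning(sprintf("MMD^2 negative beyond tolerance: %g", m2))
    m2 <- 0
  }
  sqrt(m2)
}

#' Corrected repeated k-fold cross-validation t-test
#'
#' Paired t-test on per-fold metric differences between two methods whose
#' variance is inflated by the train/test size ratio to account for the
#' dependence induced by overlapping training sets across folds:
#' `t = mean(d) / sqrt((1/(r k) + n_test/n_train) * var(d))`, with a
#' two-sided p-value from a t distribution on `r k - 1` degrees of freedom.
#'
#' @param a,b aligned per-fold metric vectors over `r` repeats times `k`
#'   folds (or pass the differences as `a` with `b = 0`).
#' @param n_train,n_test per-fold training and test set sizes.
#' @return list with `statistic`, `p_value`, `df`, `mean_diff`.
#' @export
corrected_cv_ttest <- function(a, b = 0, n_train, n_test) {
  d <- a - b
  J <- length(d)
  if (J < 2L) stop("need at least two folds")
  stopifnot(n_train > 0, n_test > 0)
  m <- mean(d)
  s2 <- stats::var(d)
  if (s2 == 0) {
    if (m == 0) return(list(statistic = 0, p_value = 1, df = J - 1L,
                            mean_diff = 0))
    return(list(statistic = sign(m) * Inf, p_value = 0, df = J - 1L,
                mean_diff = m))
  }
  tstat <- m / sqrt((1 / J + n_test / n_train) * s2)
  p <- 2 * stats::pt(-abs(tstat), df = J - 1L)
  list(statistic = tstat, p_value = p, df = J - 1L, mean_diff = m)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values, returned in the original
#' order; adjusted values are never below the raw ones and are capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
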