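#' Uniform sample weights
#' @param N a `fwmrs_dataset` (or anything with rows).
#' @return `fwmrs_sample_weights` of all 1.
#' @export
uniform_weights <- function(N) {
  n <- if (inherits(N, "fwmrs_dataset")) n_samples(N) else nrow(N)
  if (is.null(n) || n == 0L) stop("empty dataset")
  sample_weights(rep(1, n))
}

#' Run plain maximum representative subsampling
#'
#' MRS is the uniform-feature-weight special case of FW-MRS: the iterative
#' drop loop runs with every encoded column weighted exactly `1/p`, and no
#' importance estimation is performed.
#'
#' @inheritParams run_fwmrs
#' @return a `fwmrs_debias_result` with method `"mrs"`.
#' @export
run_mrs <- function(N, R, cfg = fwmrs_config()) {
  p <- ncol(N$values)
  res <- run_fwmrs(N, R, cfg,
                   feature_weights_override =
                     uniform_feature_weights(p, colnames(N$values)))
  res$method <- "mrs"
  res
}

#' Configuration for kernel mean matching
#'
#' @param sigma RBF bandwidth, or `"heuristic"` for the mean pairwise
#'   Euclidean distance over the pooled rows of N and R.
#' @param B upper bound on individual weights (default 1000).
#' @param eps slack on the sum constraint `|sum(w) - n| <= n * eps`;
#'   default `(sqrt(n) - 1)/sqrt(n)`.
#' @return object of class `fwmrs_kmm_config`.
#' @export
kmm_config <- function(sigma = "heuristic", B = 1000, eps = NULL) {
  stopifnot(B > 0)
  if (!identical(sigma, "heuristic")) {
    stopifnot(is.numeric(sigma), sigma > 0)
  }
  if (!is.null(eps)) stopifnot(eps >= 0)
  structure(list(sigma = sigma, B = B, eps = eps),
            class = "fwmrs_kmm_config")
}

rbf_gram <- function(A, B = A, sigma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Kernel mean matching sample weights
#'
#' Reweights the rows of N so that its weighted kernel mean matches R's: a
#' quadratic program `min 0.5 w' K_NN w - kappa' w` with `0 <= w <= B` and
#' `|sum(w) - n_N| <= n_N * eps`, where `kappa_i = (n_N / n_R) * sum_j
#' k(x_i, x_j^R)` and `k` is an RBF kernel whose bandwidth defaults to the
#' mean pairwise distance over the pooled rows. Solved with an interior
#' point method (`kernlab::ipop`).
#'
#' @param N encoded, standardized non-representative `fwmrs_dataset`.
#' @param R encoded, standardized representative `fwmrs_dataset`.
#' @param cfg a [kmm_config()].
#' @return `fwmrs_sample_weights` over N, with attributes `sigma` and
#'   `objective`.
#' @export
kmm_weights <- function(N, R, cfg = kmm_config()) {
  stopifnot(inherits(cfg, "fwmrs_kmm_config"))
  pooled <- pooled_domain_matrix(N, R)
  Xn <- N$values; Xr <- R$values
  nN <- nrow(Xn); nR <- nrow(Xr)
  sigma <- if (identical(cfg$sigma, "heuristic")) {
    heuristic_sigma(pooled$X)
  } else cfg$sigma
  if (!is.finite(sigma) || sigma <= 0) {
    stop("degenerate bandwidth: pooled rows are all identical")
  }
  eps <- cfg$eps %||% ((sqrt(nN) - 1) / sqrt(nN))
  K <- rbf_gram(Xn, Xn, sigma)
  K <- K + diag(1e-8, nN) # jitter for numerical positive definiteness
  kappa <- (nN / nR) * rowSums(rbf_gram(Xn, Xr, sigma))
  sol <- kernlab::ipop(
    c = matrix(-kappa, ncol = 1L), H = K,
    A = matrix(1, nrow = 1L, ncol = nN),
    b = nN * (1 - eps), r = 2 * nN * eps,
    l = matrix(0, nN, 1L), u = matrix(cfg$B, nN, 1L),
    maxiter = 200L
  )
  if (!kernlab::how(sol) %in% c("converged", "primal and dual feasible")) {
    stop(sprintf("KMM quadratic program did not converge: %s",
                 kernlab::how(sol)))
  }
  w <- pmin(pmax(as.numeric(kernlab::primal(sol)), 0), cfg$B)
  out <- sample_weights(w)
  attr(out, "sigma") <- sigma
  attr(out, "objective") <- 0.5 * drop(t(w) %*% K %*% w) - sum(kappa * w)
  out
}

#' Propensity score adjustment sample weights
#'
#' Fits an l2-regularized logistic regression for the propensity `pi` of a
#' row to belong to the non-representative sample (N labeled 1, R labeled
#' 0) and weights each N row by the inverse propensity `(1 - pi) / pi`,
#' with `pi` clipped to `(1e-6, 1 - 1e-6)`.
#'
#' @param N encoded, standardized non-representative `fwmrs_dataset`.
#' @param R encoded, standardized representative `fwmrs_dataset`.
#' @param C regularization strength; the glmnet ridge penalty is
#'   `lambda = 1 / (n * C)`.
#' @return `fwmrs_sample_weights` over N with attribute `propensity`.
#' @export
psa_weights <- function(N, R, C = 1) {
  stopifnot(is.numeric(C), C > 0)
  pooled <- pooled_domain_matrix(N, R)
  y <- 1L - pooled$y # N = 1 (participates in the non-representative sample)
  n <- nrow(pooled$X)
  lambda <- 1 / (n * C)
  fit <- glmnet::glmnet(pooled$X, y, family = "binomial", alpha = 0,
                        lambda = c(lambda * 100, lambda * 10, lambda),
                        standardize = FALSE)
  nN <- n_samples(N)
  pi_hat <- as.numeric(predict(fit, N$values, s = lambda,
                               type = "response", exact = FALSE))
  pi_hat <- pmin(pmax(pi_hat, 1e-6), 1 - 1e-6)
  out <- sample_weights(inverse_propensity(pi_hat))
  attr(out, "propensity") <- pi_hat
  out
}

#' Inverse-propensity weight transform
#' @param pi propensity of inclusion in the non-representative sample,
#'   in `(0, 1)`.
#' @return `(1 - pi) / pi`, strictly decreasing in `pi`.
#' @export
inverse_propensity <- function(pi) {
  stopifnot(all(pi > 0), all(pi < 1))
  (1 - pi) / pi
}

#' Logarithmic grid of SVM/logistic regularization strengths
#' @param from,to grid endpoints (defaults 1e-2 and 1e2).
#' @param length_out number of grid points.
#' @return numeric vector spanning `[from, to]` logarithmically.
#' @export
c_grid <- function(from = 1e-2, to = 1e2, length_out = 5L) {
  exp(seq(log(from), log(to), length.out = length_out))
}
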