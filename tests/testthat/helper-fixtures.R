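# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no data files.

# Wrap a numeric matrix as an encoded dataset.
enc_ds <- function(mat, role, outcome = NULL) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  fwmrs_dataset(mat, role = role, outcome = outcome, encoded = TRUE)
}

# Pair of encoded Gaussian datasets; `shift` displaces the first `n_shifted`
# features of N.
gaussian_pair <- function(n_N = 100L, n_R = 100L, p = 5L, shift = 0,
                          n_shifted = 1L, seed = 1L) {
  set.seed(seed)
  N <- matrix(rnorm(n_N * p), ncol = p)
  R <- matrix(rnorm(n_R * p), ncol = p)
  if (shift != 0 && n_shifted > 0L) {
    N[, seq_len(n_shifted)] <- N[, seq_len(n_shifted)] + shift
  }
  colnames(N) <- colnames(R) <- paste0("f", seq_len(p))
  list(N = enc_ds(N, "nonrepresentative"), R = enc_ds(R, "representative"))
}

# Small raw CSV on disk; returns the path.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A fast domain classifier spec for loop-heavy tests.
fast_rf_spec <- function(n_trees = 50L, seed = 1L) {
  domain_classifier_spec("random_forest", n_trees = n_trees,
                         random_seed = seed)
}

fast_cfg <- function(seed = 1L, ...) {
  fwmrs_config(classifier = fast_rf_spec(seed = seed), random_seed = seed, ...)
}

# O(n^2) pairwise AUROC oracle (ties counted one half), sample-weighted.
auroc_pairwise_oracle <- function(scores, labels, w = NULL) {
  if (is.null(w)) w <- rep(1, length(scores))
  pos <- which(labels == 1 & w > 0)
  neg <- which(labels == 0 & w > 0)
  num <- 0
  for (i in pos) for (j in neg) {
    num <- num + w[i] * w[j] *
      (if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0)
  }
  num / (sum(w[pos]) * sum(w[neg]))
}

# Quadruple-loop weighted MMD oracle following the empirical estimate
# term by term.
mmd_quadloop_oracle <- function(X, Y, wX, wY, wf, sigma) {
  k <- function(a, b) exp(-sum(wf * (a - b)^2) / (2 * sigma^2))
  wX <- wX / sum(wX); wY <- wY / sum(wY)
  s1 <- 0; s2 <- 0; s3 <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    s1 <- s1 + wX[i] * wX[j] * k(X[i, ], X[j, ])
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    s2 <- s2 + wX[i] * wY[j] * k(X[i, ], Y[j, ])
  for (i in seq_len(nrow(Y))) for (j in seq_len(nrow(Y)))
    s3 <- s3 + wY[i] * wY[j] * k(Y[i, ], Y[j, ])
  sqrt(max(s1 - 2 * s2 + s3, 0))
}

# Exact interventional Shapley values by subset enumeration: v(S) is the
# forest output with features in S taken from x and the rest from each
# background row, averaged over the background.
shapley_bruteforce_oracle <- function(forest, x, Z) {
  p <- length(x)
  vfun <- function(S) {
    Xs <- Z
    if (length(S) > 0L) Xs[, S] <- matrix(rep(x[S], each = nrow(Z)),
                                          nrow = nrow(Z))
    mean(predict(forest, Xs))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      s <- length(S)
      wgt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + wgt * (vfun(c(S, i)) - vfun(S))
    }
  }
  phi
}
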