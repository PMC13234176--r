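test_that("softmin matches the closed form and its limit cases", {
  # direct high-precision evaluation for I = (0.6, 0.4), t = 0.1:
  # w = (1/(1+e^2), e^2/(1+e^2))
  w <- softmin_weights(c(0.6, 0.4), 0.1)
  expect_equal(as.numeric(w), c(1 / (1 + exp(2)), exp(2) / (1 + exp(2))),
               tolerance = 1e-12)
  # uniform importances are a fixed point at any temperature
  for (t in c(0.001, 0.05, 0.5, 10)) {
    expect_equal(as.numeric(softmin_weights(rep(0.25, 4), t)), rep(0.25, 4))
  }
  # t -> 0+: indicator on the argmin, ties split equally
  w0 <- softmin_weights(c(0.5, 0.1, 0.4), 1e-6)
  expect_equal(as.numeric(w0), c(0, 1, 0), tolerance = 1e-9)
  wt <- softmin_weights(c(0.4, 0.1, 0.1, 0.4), 1e-7)
  expect_equal(as.numeric(wt), c(0, 0.5, 0.5, 0), tolerance = 1e-9)
  expect_error(softmin_weights(c(0.5, 0.5), 0), "positive")
  expect_error(softmin_weights(c(0.5, 0.5), -1), "positive")
})

test_that("softmin is permutation-equivariant, shift-invariant and monotone", {
  set.seed(7)
  for (rep_i in 1:20) {
    I <- runif(6)
    t <- runif(1, 0.001, 0.5)
    w <- as.numeric(softmin_weights(I, t))
    # normalization over the temperature grid scale
    expect_lt(abs(sum(w) - 1), 1e-9)
    # permutation equivariance
    perm <- sample(6)
    expect_equal(as.numeric(softmin_weights(I[perm], t)), w[perm],
                 tolerance = 1e-12)
    # invariance to adding a constant to all importances
    expect_equal(as.numeric(softmin_weights(I + 3.7, t)), w,
                 tolerance = 1e-9)
    # monotone order reversal: lower importance -> higher weight
    expect_equal(order(w), order(I, decreasing = TRUE))
  }
  # t -> Inf: uniform within 1e-6 at t = 1e6
  w_inf <- as.numeric(softmin_weights(runif(8), 1e6))
  expect_lt(max(abs(w_inf - 1 / 8)), 1e-6)
})

test_that("linear Shapley importances match the hand computation", {
  set.seed(11)
  X <- cbind(f1 = rnorm(200, sd = 1), f2 = rnorm(200, sd = 1))
  # classifier with coefficients (2, 0) on the input scale
  clf <- structure(
    list(model = structure(list(beta_raw = c(2, 0)),
                           class = "fwmrs_weighted_svm"),
         spec = domain_classifier_spec("linear_svm"),
         X = X, y = rbinom(200, 1, 0.5)),
    class = "fwmrs_domain_classifier")
  imp <- estimate_importance(clf)
  hand <- c(mean(abs(2 * (X[, 1] - mean(X[, 1])))), 0)
  expect_equal(as.numeric(imp), hand / sum(hand), tolerance = 1e-12)
  expect_equal(as.numeric(imp), c(1, 0), tolerance = 1e-12)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
})

test_that("all-zero importances fall back to uniform with a warning", {
  X <- cbind(a = rnorm(50), b = rnorm(50))
  clf <- structure(
    list(model = structure(list(beta_raw = c(0, 0)),
                           class = "fwmrs_weighted_svm"),
         spec = domain_classifier_spec("linear_svm"),
         X = X, y = rbinom(50, 1, 0.5)),
    class = "fwmrs_domain_classifier")
  expect_warning(imp <- estimate_importance(clf), "uniform")
  expect_equal(as.numeric(imp), c(0.5, 0.5))
})

test_that("interventional tree Shapley matches subset enumeration exactly", {
  set.seed(5)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p), ncol = p)
  colnames(X) <- paste0("f", 1:p)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.5) > 0)
  forest <- fit_weighted_forest(
    X, y, cfg = weighted_forest_config(n_trees = 12, random_seed = 3))
  Z <- X[1:15, , drop = FALSE]
  phi <- tree_shapley(forest, X[1:5, , drop = FALSE], Z)
  for (i in 1:5) {
    expect_equal(phi[i, ],
                 shapley_bruteforce_oracle(forest, X[i, ], Z),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # efficiency: attributions sum to f(x) - mean f(background)
  pr <- predict(forest, X[1:5, , drop = FALSE])
  expect_equal(rowSums(phi), pr - mean(predict(forest, Z)),
               tolerance = 1e-10)
})

test_that("a constant column receives zero tree importance", {
  set.seed(9)
  X <- cbind(sig = rnorm(150), const = rep(2, 150), noise = rnorm(150))
  y <- as.integer(X[, "sig"] > 0)
  forest <- fit_weighted_forest(
    X, y, cfg = weighted_forest_config(n_trees = 30, random_seed = 1))
  phi <- tree_shapley(forest, X, X[1:40, ])
  expect_equal(max(abs(phi[, "const"])), 0)
})

test_that("domain classifier discriminates shifted data but not identical data", {
  aucs_null <- aucs_shift <- numeric(20)
  for (s in 1:20) {
    pair <- gaussian_pair(300, 300, p = 5, seed = s)
    spec <- fast_rf_spec(n_trees = 100L, seed = s)
    clf <- train_domain_classifier(pair$N, pair$R, spec)
    set.seed(1000 + s)
    hold_N <- matrix(rnorm(100 * 5), ncol = 5)
    hold_R <- matrix(rnorm(100 * 5), ncol = 5)
    shifted <- gaussian_pair(300, 300, p = 5, seed = s)
    shifted$R$values[, 1] <- shifted$R$values[, 1] + 3
    clf_s <- train_domain_classifier(shifted$N, shifted$R, spec)
    hold_R_s <- hold_R; hold_R_s[, 1] <- hold_R_s[, 1] + 3
    sc <- c(predict(clf, hold_N), predict(clf, hold_R))
    sc_s <- c(predict(clf_s, hold_N), predict(clf_s, hold_R_s))
    lab <- rep(c(0, 1), each = 100)
    aucs_null[s] <- auroc(sc, lab)
    aucs_shift[s] <- auroc(sc_s, lab)
  }
  expect_gt(mean(aucs_null), 0.40)
  expect_lt(mean(aucs_null), 0.60)
  expect_gt(mean(aucs_shift), 0.9)
})

test_that("a separating feature out-imports pure noise almost always", {
  wins <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    N <- cbind(sep = rnorm(n, -2), noise = rnorm(n))
    R <- cbind(sep = rnorm(n, 2), noise = rnorm(n))
    colnames(N) <- colnames(R) <- c("sep", "noise")
    clf <- train_domain_classifier(enc_ds(N, "nonrepresentative"),
                                   enc_ds(R, "representative"),
                                   fast_rf_spec(n_trees = 50L, seed = s))
    imp <- estimate_importance(clf, n_background = 50L)
    wins[s] <- imp["sep"] > imp["noise"]
  }
  expect_gte(mean(wins), 0.95)
})

test_that("degenerate domain-classifier inputs error", {
  pair <- gaussian_pair(10, 10, seed = 1)
  empty <- pair$R
  expect_error(fwmrs_dataset(pair$R$values[0, , drop = FALSE],
                             role = "representative", encoded = TRUE),
               "no rows")
  raw <- fwmrs_dataset(data.frame(a = 1:3), role = "nonrepresentative")
  expect_error(train_domain_classifier(raw, pair$R), "encoded")
})

test_that("permutation importance ranks a separating feature first", {
  set.seed(21)
  n <- 150
  N <- cbind(sep = rnorm(n, -1.5), noise = rnorm(n))
  R <- cbind(sep = rnorm(n, 1.5), noise = rnorm(n))
  colnames(N) <- colnames(R) <- c("sep", "noise")
  clf <- train_domain_classifier(enc_ds(N, "nonrepresentative"),
                                 enc_ds(R, "representative"),
                                 fast_rf_spec(n_trees = 50L, seed = 2))
  imp <- estimate_importance(clf, method = "permutation")
  expect_gt(imp["sep"], imp["noise"])
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_equal(attr(imp, "source"), "permutation")
})
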