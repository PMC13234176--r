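test_that("zero-weight features are excluded from forest splits and SVM decisions", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  y <- as.integer(X[, 1] + X[, 3] + rnorm(n) > 0)
  fw <- feature_weights(c(0.5, 0, 0.5, 0))
  forest <- fit_weighted_forest(X, y, feature_w = fw,
                                cfg = weighted_forest_config(n_trees = 60,
                                                             random_seed = 1))
  counts <- forest_split_counts(forest)
  expect_equal(unname(counts[c(2, 4)]), c(0L, 0L))
  expect_gt(counts[1], 0)
  svm <- fit_weighted_linear_svm(scale(X), y, feature_w = fw,
                                 cfg = weighted_svm_config())
  X2 <- scale(X)
  X2[, 2] <- X2[, 2] + 100 # arbitrary change in a zero-weight column
  expect_equal(decision_values(svm, scale(X)), decision_values(svm, X2),
               tolerance = 1e-12)
})

test_that("uniform column scaling is an SVM reparameterization of C", {
  set.seed(12)
  n <- 120; p <- 3
  X <- scale(matrix(rnorm(n * p), ncol = p))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.8) > 0)
  # scaling all columns by 1/p with penalty C equals unscaled with C/p^2
  svm_scaled <- fit_weighted_linear_svm(X, y, feature_w = rep(1 / p, p),
                                        cfg = weighted_svm_config(C = 2))
  svm_plain <- fit_weighted_linear_svm(X, y, feature_w = rep(1, p),
                                       cfg = weighted_svm_config(C = 2 / p^2))
  dv_s <- decision_values(svm_scaled, X)
  dv_p <- decision_values(svm_plain, X)
  expect_equal(dv_s, dv_p, tolerance = 1e-4)
  expect_equal(order(dv_s), order(dv_p))
})

test_that("a separable cluster pair yields perfect training AUROC", {
  set.seed(3)
  X <- rbind(cbind(rnorm(40, -4, 0.3), rnorm(40)),
             cbind(rnorm(40, 4, 0.3), rnorm(40)))
  X <- scale(X)
  y <- rep(c(0L, 1L), each = 40)
  for (fw in list(c(0.9, 0.1), c(0.5, 0.5))) {
    svm <- fit_weighted_linear_svm(X, y, feature_w = fw,
                                   cfg = weighted_svm_config(C = 10))
    expect_equal(auroc(decision_values(svm, X), y), 1.0)
  }
})

test_that("duplicating a row equals doubling its weight for the SVM", {
  set.seed(8)
  n <- 60
  X <- scale(matrix(rnorm(n * 2), ncol = 2))
  y <- as.integer(X[, 1] + rnorm(n, sd = 0.6) > 0)
  w <- rep(1, n); w[5] <- 2
  svm_w <- fit_weighted_linear_svm(X, y, sample_w = w,
                                   cfg = weighted_svm_config(C = 1))
  Xd <- rbind(X, X[5, , drop = FALSE])
  yd <- c(y, y[5])
  svm_d <- fit_weighted_linear_svm(Xd, yd, cfg = weighted_svm_config(C = 1))
  expect_equal(svm_w$beta, svm_d$beta, tolerance = 1e-4)
  expect_equal(svm_w$objective, svm_d$objective, tolerance = 1e-4)
})

test_that("single-class inputs are rejected by both learners", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_weighted_forest(X, rep(1L, 10)), "both classes")
  expect_error(fit_weighted_linear_svm(X, rep(0L, 10)), "both classes")
  # zero-weight rows can induce a single class among active rows
  y <- c(rep(0L, 5), rep(1L, 5))
  sw <- c(rep(1, 5), rep(0, 5))
  expect_error(fit_weighted_forest(X, y, sample_w = sw), "both classes")
  expect_error(fit_weighted_forest(X, y, sample_w = rep(0, 10)), "zero")
  expect_error(fit_weighted_forest(X, y, feature_w = rep(0, 2)), "zero")
})

test_that("auroc matches the pairwise oracle, with ties and weights", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 1))))
  expect_true(is.na(auroc(c(0.1, 0.9), c(1, 0), sample_w = c(1, 0))))
  set.seed(17)
  for (rep_i in 1:5) {
    s <- sample(round(runif(50), 2)) # rounded scores force ties
    lab <- rbinom(50, 1, 0.5)
    if (length(unique(lab)) < 2) lab[1] <- 1 - lab[1]
    w <- runif(50); w[sample(50, 5)] <- 0
    expect_equal(auroc(s, lab), auroc_pairwise_oracle(s, lab),
                 tolerance = 1e-12)
    expect_equal(auroc(s, lab, sample_w = w),
                 auroc_pairwise_oracle(s, lab, w), tolerance = 1e-12)
    # complement symmetry (ties counted one half keep it exact)
    expect_equal(auroc(-s, lab), 1 - auroc(s, lab), tolerance = 1e-12)
    expect_equal(auroc(-s, lab, sample_w = w),
                 1 - auroc(s, lab, sample_w = w), tolerance = 1e-12)
  }
})

test_that("the uniform-weight forest tracks an independent forest implementation", {
  skip_if_not_installed("ranger")
  set.seed(14)
  n <- 300
  X <- matrix(rnorm(n * 4), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  y <- as.integer(X[, 1] + 0.6 * X[, 2] + rnorm(n, sd = 0.8) > 0)
  Xt <- matrix(rnorm(200 * 4), ncol = 4)
  colnames(Xt) <- colnames(X)
  yt <- as.integer(Xt[, 1] + 0.6 * Xt[, 2] + rnorm(200, sd = 0.8) > 0)
  native <- fit_weighted_forest(
    X, y, cfg = weighted_forest_config(n_trees = 200, random_seed = 5))
  auc_native <- auroc(predict(native, Xt), yt)
  rg <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                       probability = TRUE, num.trees = 200, seed = 5,
                       num.threads = 1)
  pr <- predict(rg, as.data.frame(Xt))$predictions[, "1"]
  auc_ranger <- auroc(pr, yt)
  expect_gt(auc_native, 0.8)
  expect_lt(abs(auc_native - auc_ranger), 0.05)
})

test_that("forest candidate selection follows the feature weights", {
  # pure-noise response so split quality cannot mask the sampling law
  set.seed(6)
  n <- 250
  X <- matrix(rnorm(n * 3), ncol = 3)
  colnames(X) <- paste0("f", 1:3)
  y <- rbinom(n, 1, 0.5)
  fw <- feature_weights(c(0.8, 0.1, 0.1))
  forest <- fit_weighted_forest(
    X, y, feature_w = fw,
    cfg = weighted_forest_config(n_trees = 200, candidate_features_per_split = 1,
                                 random_seed = 42))
  counts <- forest_split_counts(forest)
  total <- sum(counts)
  phat <- counts[1] / total
  # within 3 sd of the multinomial expectation
  se <- sqrt(0.8 * 0.2 / total)
  expect_lt(abs(phat - 0.8), 3 * se)
})
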