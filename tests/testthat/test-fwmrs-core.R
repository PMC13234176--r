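test_that("cv_round separates disjoint supports perfectly", {
  set.seed(2)
  N <- matrix(runif(40, 0, 1), ncol = 1)
  R <- matrix(runif(40, 5, 6), ncol = 1)
  colnames(N) <- colnames(R) <- "x"
  cfg <- fast_cfg(seed = 3)
  out <- cv_round(N, R, uniform_feature_weights(1, "x"), cfg)
  expect_equal(out$mean_auroc, 1.0)
  expect_equal(length(out$oof_scores), 40L)
  expect_true(all(!is.na(out$oof_scores)))
})

test_that("cv_round sits near chance when N duplicates R's distribution", {
  aucs <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    base <- matrix(rnorm(80 * 3), ncol = 3)
    colnames(base) <- paste0("f", 1:3)
    idx <- sample(80, 40)
    out <- cv_round(base[idx, ], base[-idx, ],
                    uniform_feature_weights(3, colnames(base)),
                    fast_cfg(seed = s), seed = s)
    aucs[s] <- out$mean_auroc
  }
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("cv_round fold assignment is reproducible bit-exactly", {
  pair <- gaussian_pair(4, 4, p = 2, seed = 9)
  cfg <- fast_cfg(seed = 5, k = 2L)
  a <- cv_round(pair$N$values, pair$R$values, uniform_feature_weights(2),
                cfg, seed = 77)
  b <- cv_round(pair$N$values, pair$R$values, uniform_feature_weights(2),
                cfg, seed = 77)
  expect_identical(a, b)
})

test_that("the loop exits infeasible with no weights when too few rows remain", {
  pair <- gaussian_pair(3, 30, p = 2, seed = 1)
  res <- run_fwmrs(pair$N, pair$R, fast_cfg(seed = 1, d = 3L),
                   feature_weights_override = uniform_feature_weights(2))
  expect_equal(res$status, "infeasible")
  expect_null(res$sample_weights)
  expect_null(res$feature_weights)
})

test_that("a separated fixture drops until infeasible or terminates within the attrition bound", {
  # disjoint supports stay separable no matter how many rows are dropped,
  # so the loop must hit the infeasibility guard, never loop forever
  set.seed(13)
  N <- matrix(rnorm(20, -6), ncol = 1); R <- matrix(rnorm(60, 6), ncol = 1)
  colnames(N) <- colnames(R) <- "x"
  res <- run_fwmrs(enc_ds(N, "nonrepresentative"), enc_ds(R, "representative"),
                   fast_cfg(seed = 2, d = 2L),
                   feature_weights_override = uniform_feature_weights(1, "x"))
  expect_equal(res$status, "infeasible")
  expect_lte(nrow(res$trace), floor((20 - 1) / 2) + 1)
})

test_that("drops are disjoint, monotone, and the trace obeys the stopping rule", {
  pair <- gaussian_pair(60, 60, p = 3, shift = 1.5, seed = 4)
  res <- run_fwmrs(pair$N, pair$R, fast_cfg(seed = 4, d = 2L),
                   feature_weights_override = uniform_feature_weights(3))
  expect_equal(res$status, "converged")
  seq_drop <- drop_sequence(res)
  expect_equal(anyDuplicated(seq_drop), 0L)
  expect_equal(sum(res$sample_weights == 0), length(seq_drop))
  expect_setequal(which(res$sample_weights == 0), seq_drop)
  tr <- res$trace
  n_iter <- nrow(tr)
  expect_lte(tr$mean_auroc[n_iter], 0.5)
  if (n_iter > 1L) expect_true(all(tr$mean_auroc[-n_iter] > 0.5))
  expect_equal(tr$n_dropped_total,
               cumsum(c(rep(2L, n_iter - 1L), 0L)))
})

test_that("identical runs are bit-identical and MRS equals the uniform override", {
  pair <- gaussian_pair(40, 40, p = 3, shift = 1, seed = 6)
  cfg <- fast_cfg(seed = 11, d = 1L)
  r1 <- run_fwmrs(pair$N, pair$R, cfg,
                  feature_weights_override = uniform_feature_weights(3))
  r2 <- run_fwmrs(pair$N, pair$R, cfg,
                  feature_weights_override = uniform_feature_weights(3))
  expect_identical(r1$trace, r2$trace)
  expect_identical(as.numeric(r1$sample_weights), as.numeric(r2$sample_weights))
  m <- run_mrs(pair$N, pair$R, cfg)
  expect_identical(drop_sequence(m), drop_sequence(r1))
  expect_equal(as.numeric(m$feature_weights), rep(1 / 3, 3))
})

test_that("the max_iterations guard is signaled distinctly from infeasibility", {
  pair <- gaussian_pair(30, 30, p = 2, shift = 6, seed = 2)
  cfg <- fast_cfg(seed = 2, d = 1L)
  cfg$max_iterations <- 2L
  expect_error(run_fwmrs(pair$N, pair$R, cfg,
                         feature_weights_override = uniform_feature_weights(2)),
               "max_iterations exceeded")
})

test_that("schema mismatch between N and R is rejected", {
  pair <- gaussian_pair(10, 10, p = 2, seed = 1)
  other <- gaussian_pair(10, 10, p = 3, seed = 1)
  expect_error(run_fwmrs(pair$N, other$R, fast_cfg()), "mismatch|space")
})
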