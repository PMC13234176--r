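test_that("the population generator hits its logistic prevalence", {
  spec0 <- population_spec(outcome_coef = 0, outcome_intercept = 0)
  d <- generate_population(spec0, 5000, seed = 3)
  # binomial 99% band around 0.5 at n = 5000
  expect_lt(abs(mean(d$outcome) - 0.5), 2.58 * sqrt(0.25 / 5000))
  spec_neg <- population_spec(outcome_coef = 0, outcome_intercept = -20)
  expect_lt(mean(generate_population(spec_neg, 2000, seed = 3)$outcome), 0.01)
  a <- generate_population(population_spec(), 200, seed = 5)
  b <- generate_population(population_spec(), 200, seed = 5)
  expect_identical(a$values, b$values)
  expect_identical(a$outcome, b$outcome)
})

test_that("bias injection retains exactly ceil(rho * n_pos) positives", {
  df <- data.frame(x = rnorm(300))
  y <- c(rep(1L, 100), rep(0L, 200))
  d <- fwmrs_dataset(df, role = "test", outcome = y)
  b <- inject_bias(d, bias_spec(0.10, random_seed = 2))
  expect_equal(sum(b$outcome == 1), 10L)
  expect_equal(sum(b$outcome == 0), 200L)
  # retained rows are a subset in original order
  src <- attr(b, "source_rows")
  expect_true(all(diff(src) > 0))
  expect_equal(b$values$x, df$x[src])
  # rho = 1 keeps everything; negatives never change
  expect_equal(n_samples(inject_bias(d, bias_spec(1, 1))), 300L)
  for (rho in c(0.25, 0.5, 0.9)) {
    expect_equal(sum(inject_bias(d, bias_spec(rho, 1))$outcome == 0), 200L)
    expect_equal(sum(inject_bias(d, bias_spec(rho, 1))$outcome == 1),
                 ceiling(rho * 100))
  }
  d0 <- fwmrs_dataset(df, role = "test", outcome = rep(0L, 300))
  expect_error(inject_bias(d0), "no positive")
})

test_that("make_split produces disjoint N/R/T with the stated sizes", {
  d <- generate_population(population_spec(), 1000, seed = 7)
  s <- make_split(d, repeat_seed = 3, fold = 2)
  expect_equal(n_samples(s$T), 200L)
  expect_equal(n_samples(s$R), 400L)
  expect_lte(n_samples(s$N), 400L)
  expect_null(s$R$outcome) # outcome withheld structurally
  expect_false(is.null(s$N$outcome))
  expect_false(is.null(s$T$outcome))
  s2 <- make_split(d, repeat_seed = 3, fold = 2)
  expect_identical(s$N$values, s2$N$values)
  expect_identical(s$T$values, s2$T$values)
  expect_error(make_split(generate_population(population_spec(), 4, seed = 1),
                          1, 1, n_folds = 5), "fewer rows")
})

test_that("run_experiment records uniform weighting as dropping nothing", {
  d <- generate_population(population_spec(), 300, seed = 9)
  plan <- experiment_plan(methods = "uniform", n_repeats = 1L,
                          downstream_trees = 50L, domain_trees = 30L,
                          master_seed = 4)
  res <- run_experiment(d, plan)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$dropped_fraction == 0))
  expect_true(all(res$status == "converged"))
  expect_true(all(res$test_auroc > 0 & res$test_auroc <= 1))
  # bit-identical reproduction under the same master seed
  res2 <- run_experiment(d, plan)
  expect_identical(res, res2)
})

test_that("the unbiased reference arm beats training on the biased half", {
  spec <- population_spec(outcome_coef = c(2, 1.5, 0, 0))
  d <- generate_population(spec, 600, seed = 21)
  plan <- experiment_plan(methods = c("uniform", "unbiased"), n_repeats = 1L,
                          downstream_trees = 100L, domain_trees = 30L,
                          master_seed = 2)
  res <- run_experiment(d, plan)
  su <- summarize_experiment(res)
  expect_gte(su$test_auroc_mean[su$method == "unbiased"],
             su$test_auroc_mean[su$method == "uniform"])
  expect_error(experiment_plan(methods = "nonsense"), "unknown method")
})

test_that("compare_methods pairs runs and returns a corrected test", {
  res <- data.frame(method = rep(c("a", "b"), each = 6),
                    repeat_idx = rep(rep(1:2, each = 3), 2),
                    fold = rep(1:3, 4),
                    status = "converged",
                    test_auroc = c(0.8, 0.82, 0.79, 0.81, 0.80, 0.83,
                                   0.78, 0.80, 0.77, 0.80, 0.78, 0.81),
                    n_train = 100, n_test = 25)
  out <- compare_methods(res, "a", "b")
  d <- res$test_auroc[1:6] - res$test_auroc[7:12]
  ref <- mean(d) / sqrt(var(d) * (1 / 6 + 25 / 100))
  expect_equal(out$statistic, ref, tolerance = 1e-12)
})

test_that("temperature_sweep emits one row per setting and an MRS baseline", {
  pair <- gaussian_pair(30, 30, p = 3, shift = 1.5, seed = 5)
  out <- temperature_sweep(pair$N, pair$R, grid = 0.05,
                           cfg = fast_cfg(seed = 3, n_background = 40L),
                           n_runs = 2L)
  expect_equal(nrow(out$summary), 2L) # t = 0.05 and the MRS row
  expect_true("mrs" %in% out$summary$setting)
  expect_equal(nrow(out$runs), 4L)
  expect_true(all(c("n_dropped", "mmd_uniform", "mmd_feature_weighted")
                  %in% names(out$runs)))
})
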