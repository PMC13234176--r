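#' Specification of a synthetic survey population
#'
#' Emulates the kind of tabular social/life-science data the debiasing
#' methods target: independent Gaussian numeric features, multinomial
#' categorical features, and a binary outcome from a logistic model on the
#' numeric features. Per-feature shift/scale knobs describe a distribution-
#' shifted sub-population (used to create fixtures where some features are
#' strongly biased while others are representative).
#'
#' @param n_numeric number of numeric features.
#' @param n_categorical number of categorical features.
#' @param category_levels levels per categorical feature (recycled).
#' @param outcome_coef logistic coefficients over the numeric features
#'   (recycled/truncated to `n_numeric`). The default gives every numeric
#'   feature some predictive strength, graded from strong to weak, so that
#'   undersampling one outcome class biases all of them to differing
#'   degrees — the regime feature weighting is designed for.
#' @param outcome_intercept logistic intercept.
#' @param shift per-numeric-feature mean shift of the shifted sub-population.
#' @param scale per-numeric-feature sd of the shifted sub-population.
#' @return object of class `fwmrs_population_spec`.
#' @export
population_spec <- function(n_numeric = 4L, n_categorical = 1L,
                            category_levels = 3L,
                            outcome_coef = 1.5 / 2^(seq_len(n_numeric) - 1L),
                            outcome_intercept = 0,
                            shift = rep(0, n_numeric),
                            scale = rep(1, n_numeric)) {
  stopifnot(n_numeric + n_categorical >= 1L, all(scale > 0))
  outcome_coef <- rep_len(outcome_coef, n_numeric)
  shift <- rep_len(shift, n_numeric)
  scale <- rep_len(scale, n_numeric)
  category_levels <- rep_len(as.integer(category_levels),
                             max(1L, n_categorical))
  structure(
    list(n_numeric = as.integer(n_numeric),
         n_categorical = as.integer(n_categorical),
         category_levels = category_levels,
         outcome_coef = outcome_coef,
         outcome_intercept = outcome_intercept,
         shift = shift, scale = scale),
    class = "fwmrs_population_spec"
  )
}

#' Draw a synthetic population sample
#'
#' @param spec a [population_spec()].
#' @param n number of rows.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param shifted if `TRUE`, numeric features are drawn from the shifted
#'   sub-population (`N(shift_j, scale_j^2)` instead of `N(0, 1)`).
#' @param role role tag of the returned dataset.
#' @return a raw `fwmrs_dataset` with a binary outcome.
#' @export
generate_population <- function(spec, n, seed = 1L, shifted = FALSE,
                                role = "test") {
  stopifnot(inherits(spec, "fwmrs_population_spec"), n > 0)
  with_local_seed(seed, {
    df <- list()
    for (j in seq_len(spec$n_numeric)) {
      df[[paste0("num", j)]] <- if (shifted) {
        stats::rnorm(n, spec$shift[j], spec$scale[j])
      } else stats::rnorm(n)
    }
    for (j in seq_len(spec$n_categorical)) {
      lv <- paste0("l", seq_len(spec$category_levels[j]))
      df[[paste0("cat", j)]] <- sample(lv, n, replace = TRUE)
    }
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    num <- as.matrix(df[, seq_len(spec$n_numeric), drop = FALSE])
    eta <- spec$outcome_intercept + drop(num %*% spec$outcome_coef)
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    fwmrs_dataset(df, role = role, outcome = y)
  })
}

#' Specification of an artificial biasing mechanism
#'
#' The supported mechanism undersamples the positive outcome class,
#' retaining a fraction `retained_fraction` of the original positives —
#' emulating, e.g., an underdiagnosed medical condition that misrepresents
#' prevalence.
#'
#' @param retained_fraction fraction of positive rows kept, in `(0, 1]`.
#' @param random_seed subsample seed.
#' @return object of class `fwmrs_bias_spec`.
#' @export
bias_spec <- function(retained_fraction = 0.1, random_seed = 1L) {
  stopifnot(retained_fraction > 0, retained_fraction <= 1)
  structure(list(mechanism = "undersample_positive",
                 retained_fraction = retained_fraction,
                 random_seed = as.integer(random_seed)),
            class = "fwmrs_bias_spec")
}

#' Inject selection bias by undersampling the positive class
#'
#' Keeps a seeded uniform subsample of `ceiling(rho * n_pos)` positive rows
#' and every negative row; row order is preserved.
#'
#' @param data a `fwmrs_dataset` with an outcome.
#' @param spec a [bias_spec()].
#' @return the biased `fwmrs_dataset` (role set to `"nonrepresentative"`).
#' @export
inject_bias <- function(data, spec = bias_spec()) {
  stopifnot(inherits(data, "fwmrs_dataset"), inherits(spec, "fwmrs_bias_spec"))
  if (is.null(data$outcome)) stop("bias injection requires an outcome")
  pos <- which(data$outcome == 1L)
  if (length(pos) == 0L) stop("no positive rows to undersample")
  n_keep <- ceiling(spec$retained_fraction * length(pos))
  keep_pos <- with_local_seed(spec$random_seed,
                             sort(sample(pos, n_keep)))
  keep <- sort(c(keep_pos, which(data$outcome == 0L)))
  out <- dataset_rows(data, keep)
  out$role <- "nonrepresentative"
  attr(out, "source_rows") <- keep
  out
}

#' Build one N/R/T split of a labeled dataset
#'
#' Partitions the rows into `n_folds` folds (seeded by `repeat_seed`); the
#' requested fold is the untouched test set T. The remaining training rows
#' are shuffled and split in half: one half receives the artificial bias
#' and becomes the non-representative dataset N (outcome kept); the other
#' half becomes the representative dataset R, whose outcome is withheld
#' structurally so it cannot leak into training.
#'
#' @param data a raw `fwmrs_dataset` with an outcome.
#' @param repeat_seed seed for the fold partition and the half split.
#' @param fold which fold (1..n_folds) to hold out as T.
#' @param n_folds number of folds (default 5).
#' @param bias a [bias_spec()].
#' @return list with raw datasets `N`, `R`, `T`.
#' @export
make_split <- function(data, repeat_seed = 1L, fold = 1L, n_folds = 5L,
                       bias = bias_spec()) {
  stopifnot(inherits(data, "fwmrs_dataset"), fold >= 1L, fold <= n_folds)
  if (is.null(data$outcome)) stop("make_split requires an outcome")
  n <- n_samples(data)
  if (n < n_folds) stop("fewer rows than folds")
  folds <- with_local_seed(derive_seed(repeat_seed, 1L),
                          sample(rep_len(seq_len(n_folds), n)))
  test_idx <- which(folds == fold)
  train_idx <- which(folds != fold)
  train_idx <- with_local_seed(derive_seed(repeat_seed, 2L + fold),
                              sample(train_idx))
  half <- floor(length(train_idx) / 2)
  n_idx <- sort(train_idx[seq_len(half)])
  r_idx <- sort(train_idx[-seq_len(half)])
  N_unbiased <- dataset_rows(data, n_idx)
  N_unbiased$role <- "nonrepresentative"
  N <- inject_bias(N_unbiased, bias_spec(bias$retained_fraction,
                                         derive_seed(repeat_seed, 50L + fold)))
  R <- dataset_rows(data, r_idx)
  R$outcome <- NULL
  R$role <- "representative"
  T_ <- dataset_rows(data, test_idx)
  T_$role <- "test"
  list(N = N, R = R, T = T_, N_unbiased = N_unbiased)
}

#' Plan for the synthetic benchmark experiment
#'
#' Defaults mirror the study conditions: 10 repeats of 5-fold
#' cross-validation, positives in N undersampled to 10%, a 9-point
#' temperature grid, min-weight-fraction-per-leaf grid
#' `[0.025, 0.01, 0.001, 0]`, a logarithmic C grid over `[1e-2, 1e2]`, a
#' 500-tree downstream forest, 5 drops per iteration for datasets larger
#' than the 6000-row subsample cap and 1 otherwise, and CV AUROC over N as
#' the selection criterion. Shrink the grids and repeats for smoke runs.
#'
#' @param methods subset of `c("uniform", "mrs", "fwmrs_rf", "fwmrs_svm",
#'   "kmm", "psa")`, plus the pseudo-method `"unbiased"` (downstream model
#'   trained on the un-biased training half; a reference arm, not a
#'   debiasing method).
#' @param n_repeats,n_folds repeated CV structure.
#' @param retained_fraction positive-class retention of the bias injector.
#' @param temperature_grid softmin temperatures searched for FW-MRS.
#' @param min_leaf_grid minimum weight fraction per leaf grid (forests).
#' @param C_grid regularization grid (SVM variant and PSA).
#' @param downstream_trees trees in the downstream forest.
#' @param downstream_cv_folds folds of the selection CV over N.
#' @param subsample_cap rows above which the dataset is subsampled and the
#'   per-iteration drop count becomes `d_large`.
#' @param d_small,d_large drops per iteration for small/large datasets.
#' @param domain_trees trees in the domain classifier.
#' @param master_seed seed from which all per-repeat seeds derive.
#' @return object of class `fwmrs_experiment_plan`.
#' @export
experiment_plan <- function(methods = c("uniform", "mrs", "fwmrs_rf"),
                            n_repeats = 10L, n_folds = 5L,
                            retained_fraction = 0.1,
                            temperature_grid = c(0.001, 0.0025, 0.005, 0.01,
                                                 0.025, 0.05, 0.1, 0.25, 0.5),
                            min_leaf_grid = c(0.025, 0.01, 0.001, 0),
                            C_grid = c_grid(),
                            downstream_trees = 500L,
                            downstream_cv_folds = 5L,
                            subsample_cap = 6000L,
                            d_small = 1L, d_large = 5L,
                            domain_trees = 200L,
                            master_seed = 1L) {
  known <- c("uniform", "mrs", "fwmrs_rf", "fwmrs_svm", "kmm", "psa",
             "unbiased")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown method '%s'; valid methods: %s",
                 bad[1L], paste(known, collapse = ", ")))
  }
  stopifnot(n_repeats >= 1L, n_folds >= 2L,
            length(temperature_grid) >= 1L, length(min_leaf_grid) >= 1L,
            length(C_grid) >= 1L)
  structure(
    list(methods = methods, n_repeats = as.integer(n_repeats),
         n_folds = as.integer(n_folds),
         retained_fraction = retained_fraction,
         temperature_grid = temperature_grid,
         min_leaf_grid = min_leaf_grid, C_grid = C_grid,
         downstream_trees = as.integer(downstream_trees),
         downstream_cv_folds = as.integer(downstream_cv_folds),
         subsample_cap = as.integer(subsample_cap),
         d_small = as.integer(d_small), d_large = as.integer(d_large),
         domain_trees = as.integer(domain_trees),
         master_seed = as.integer(master_seed)),
    class = "fwmrs_experiment_plan"
  )
}

# Downstream selection criterion: weighted-forest CV AUROC over N.
downstream_cv_auroc <- function(Xn, yn, sw, fw, trees, min_leaf, k, seed) {
  active <- which(sw > 0)
  if (length(active) < 2L * k) return(NA_real_)
  folds <- with_local_seed(derive_seed(seed, 3L),
                          sample(rep_len(seq_len(k), length(active))))
  aucs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- active[folds != f]; ho <- active[folds == f]
    if (length(unique(yn[tr])) < 2L || length(unique(yn[ho])) < 2L) next
    fit <- fit_weighted_forest(
      Xn[tr, , drop = FALSE], yn[tr], sample_w = sw[tr], feature_w = fw,
      cfg = weighted_forest_config(n_trees = trees,
                                   min_weight_fraction_leaf = min_leaf,
                                   random_seed = derive_seed(seed, 200L + f)))
    sc <- predict(fit, Xn[ho, , drop = FALSE])
    aucs[f] <- auroc(sc, yn[ho], sample_w = sw[ho])
  }
  if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
}

run_method_on_split <- function(method, enc, plan, d, seed) {
  # returns list(sw, fw, status, params) after grid selection over N
  Xn <- enc$N$values; yn <- enc$N$outcome
  p <- ncol(Xn)
  unif_fw <- uniform_feature_weights(p, colnames(Xn))
  spec_rf <- function(ml) domain_classifier_spec(
    "random_forest", n_trees = plan$domain_trees,
    min_weight_fraction_leaf = ml, random_seed = seed)
  candidates <- switch(
    method,
    uniform = list(list(sw = rep(1, nrow(Xn)), fw = unif_fw,
                        status = "converged", params = list())),
    unbiased = list(list(sw = rep(1, nrow(Xn)), fw = unif_fw,
                         status = "converged", params = list())),
    kmm = list(local({
      w <- kmm_weights(enc$N_std, enc$R_std)
      list(sw = as.numeric(w), fw = unif_fw, status = "converged",
           params = list(sigma = attr(w, "sigma")))
    })),
    psa = lapply(plan$C_grid, function(C) {
      w <- psa_weights(enc$N_std, enc$R_std, C = C)
      list(sw = as.numeric(w), fw = unif_fw, status = "converged",
           params = list(C = C))
    }),
    mrs = lapply(plan$min_leaf_grid, function(ml) {
      res <- run_mrs(enc$N, enc$R,
                     fwmrs_config(k = 5L, d = d, classifier = spec_rf(ml),
                                  random_seed = seed))
      result_candidate(res, list(min_leaf = ml))
    }),
    fwmrs_rf = {
      grid <- expand.grid(t = plan$temperature_grid, ml = plan$min_leaf_grid)
      lapply(seq_len(nrow(grid)), function(i) {
        res <- run_fwmrs(enc$N, enc$R,
                         fwmrs_config(temperature = grid$t[i], k = 5L, d = d,
                                      classifier = spec_rf(grid$ml[i]),
                                      random_seed = seed))
        result_candidate(res, list(temperature = grid$t[i],
                                   min_leaf = grid$ml[i]))
      })
    },
    fwmrs_svm = {
      grid <- expand.grid(t = plan$temperature_grid, C = plan$C_grid)
      lapply(seq_len(nrow(grid)), function(i) {
        spec <- domain_classifier_spec("linear_svm", C = grid$C[i],
                                       random_seed = seed)
        res <- run_fwmrs(enc$N_std, enc$R_std,
                         fwmrs_config(temperature = grid$t[i], k = 5L, d = d,
                                      classifier = spec, random_seed = seed))
        result_candidate(res, list(temperature = grid$t[i], C = grid$C[i]))
      })
    },
    stop(sprintf("unknown method '%s'", method))
  )
  candidates <- Filter(Negate(is.null), candidates)
  feasible <- Filter(function(c) c$status == "converged", candidates)
  if (length(feasible) == 0L) {
    return(list(sw = NULL, fw = NULL, status = "infeasible", params = list()))
  }
  if (length(feasible) == 1L) return(feasible[[1L]])
  crit <- vapply(feasible, function(c)
    downstream_cv_auroc(Xn, yn, c$sw, c$fw, plan$downstream_trees,
                        plan$min_leaf_grid[1L], plan$downstream_cv_folds,
                        seed),
    numeric(1))
  if (all(is.na(crit))) return(feasible[[1L]])
  feasible[[which.max(crit)]]
}

result_candidate <- function(res, params) {
  if (res$status != "converged") {
    return(list(sw = NULL, fw = NULL, status = res$status, params = params))
  }
  list(sw = as.numeric(res$sample_weights),
       fw = res$feature_weights, status = "converged", params = params)
}

encode_split <- function(split) {
  map <- fit_encoding(list(split$N, split$R))
  list(N = apply_encoding(split$N, map),
       R = apply_encoding(split$R, map),
       T = apply_encoding(split$T, map),
       N_std = apply_encoding(split$N, map, standardize = TRUE),
       R_std = apply_encoding(split$R, map, standardize = TRUE),
       T_std = apply_encoding(split$T, map, standardize = TRUE),
       map = map)
}

#' Run the full synthetic-bias benchmark
#'
#' For every repeat and fold: builds the N/R/T split with the artificial
#' bias, runs every method in the plan (with grid search over its
#' hyperparameters, selected by weighted-forest CV AUROC over N), trains
#' the downstream feature- and sample-weighted forest on all of N, and
#' records the test AUROC on T, the dropped-sample fraction, and the
#' weighted MMD between reweighted N and T before and after debiasing. T is
#' materialized after all fitting and never influences training or
#' selection.
#'
#' @param data a raw `fwmrs_dataset` with an outcome.
#' @param plan an [experiment_plan()].
#' @return data.frame with one row per (repeat, fold, method): columns
#'   `method, repeat_idx, fold, status, test_auroc, dropped_fraction,
#'   mmd_pre, mmd_post, n_train, n_test`.
#' @export
run_experiment <- function(data, plan = experiment_plan()) {
  stopifnot(inherits(data, "fwmrs_dataset"),
            inherits(plan, "fwmrs_experiment_plan"))
  if (is.null(data$outcome)) stop("run_experiment requires an outcome")
  n0 <- n_samples(data)
  d <- if (n0 > plan$subsample_cap) plan$d_large else plan$d_small
  if (n0 > plan$subsample_cap) {
    idx <- with_local_seed(derive_seed(plan$master_seed, 99L),
                          sort(sample.int(n0, plan$subsample_cap)))
    data <- dataset_rows(data, idx)
  }
  rows <- list()
  for (rep_i in seq_len(plan$n_repeats)) {
    rep_seed <- derive_seed(plan$master_seed, 1000L + rep_i)
    for (fold in seq_len(plan$n_folds)) {
      split <- make_split(data, repeat_seed = rep_seed, fold = fold,
                          n_folds = plan$n_folds,
                          bias = bias_spec(plan$retained_fraction))
      enc <- encode_split(split)
      run_seed <- derive_seed(rep_seed, fold)
      for (method in plan$methods) {
        sel <- run_method_on_split(method, enc, plan, d, run_seed)
        rows[[length(rows) + 1L]] <-
          evaluate_method_row(method, sel, split, enc, plan, rep_i, fold,
                              run_seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

evaluate_method_row <- function(method, sel, split, enc, plan, rep_i, fold,
                                seed) {
  base <- data.frame(method = method, repeat_idx = rep_i, fold = fold,
                     status = sel$status, test_auroc = NA_real_,
                     dropped_fraction = NA_real_, mmd_pre = NA_real_,
                     mmd_post = NA_real_,
                     n_train = n_samples(split$N),
                     n_test = n_samples(split$T),
                     stringsAsFactors = FALSE)
  if (sel$status != "converged") return(base)
  if (method == "unbiased") {
    # reference arm: downstream model trained on the training half before
    # bias injection; measures the cost of the injected bias itself
    Nu <- apply_encoding(split$N_unbiased, enc$map)
    fit <- fit_weighted_forest(
      Nu$values, Nu$outcome,
      feature_w = uniform_feature_weights(ncol(Nu$values)),
      cfg = weighted_forest_config(n_trees = plan$downstream_trees,
                                   min_weight_fraction_leaf =
                                     plan$min_leaf_grid[1L],
                                   random_seed = derive_seed(seed, 7L)))
    base$test_auroc <- auroc(predict(fit, enc$T$values), split$T$outcome)
    base$dropped_fraction <- 0
    return(base)
  }
  Xn <- enc$N$values; yn <- enc$N$outcome
  sw <- sel$sw
  fit <- fit_weighted_forest(
    Xn, yn, sample_w = sw, feature_w = sel$fw,
    cfg = weighted_forest_config(n_trees = plan$downstream_trees,
                                 min_weight_fraction_leaf =
                                   plan$min_leaf_grid[1L],
                                 random_seed = derive_seed(seed, 7L)))
  sc <- predict(fit, enc$T$values)
  base$test_auroc <- auroc(sc, split$T$outcome)
  base$dropped_fraction <- mean(sw == 0)
  sig <- heuristic_sigma(rbind(enc$N_std$values, enc$T_std$values))
  base$mmd_pre <- weighted_mmd(enc$N_std$values, enc$T_std$values,
                               sigma = sig)
  base$mmd_post <- weighted_mmd(enc$N_std$values, enc$T_std$values,
                                w_X = sw, sigma = sig)
  base
}

#' Per-method summary of a benchmark result table
#' @param results output of [run_experiment()].
#' @return data.frame of means and standard deviations per method.
#' @export
summarize_experiment <- function(results) {
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  methods <- unique(results$method)
  out <- lapply(methods, function(m) {
    r <- results[results$method == m, ]
    data.frame(method = m,
               n_runs = nrow(r),
               n_infeasible = sum(r$status != "converged"),
               test_auroc_mean = agg(r$test_auroc)[1L],
               test_auroc_sd = agg(r$test_auroc)[2L],
               dropped_mean = agg(r$dropped_fraction)[1L],
               dropped_sd = agg(r$dropped_fraction)[2L],
               mmd_pre_mean = agg(r$mmd_pre)[1L],
               mmd_post_mean = agg(r$mmd_post)[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Corrected t-test comparison between two methods of a benchmark table
#'
#' Pairs the per-(repeat, fold) test AUROCs of two methods and applies the
#' corrected repeated k-fold CV t-test; apply [benjamini_hochberg()] across
#' datasets when several tables are compared.
#'
#' @param results output of [run_experiment()].
#' @param method_a,method_b method names present in `results`.
#' @return the [corrected_cv_ttest()] result.
#' @export
compare_methods <- function(results, method_a, method_b) {
  ra <- results[results$method == method_a, ]
  rb <- results[results$method == method_b, ]
  key <- function(r) paste(r$repeat_idx, r$fold)
  common <- intersect(key(ra), key(rb))
  ra <- ra[match(common, key(ra)), ]
  rb <- rb[match(common, key(rb)), ]
  ok <- !is.na(ra$test_auroc) & !is.na(rb$test_auroc)
  corrected_cv_ttest(ra$test_auroc[ok], rb$test_auroc[ok],
                     n_train = round(mean(ra$n_train[ok])),
                     n_test = round(mean(ra$n_test[ok])))
}

#' Temperature sweep of FW-MRS on one N/R pair
#'
#' Runs FW-MRS across a temperature grid with shared seeds (the domain
#' classifier and its importances are computed once per run and reused for
#' every temperature, since the softmin input does not depend on `t`), plus
#' an MRS baseline row, and reports the trade-off between dropped samples
#' and distribution alignment: per temperature the mean and sd of the
#' dropped count and of the weighted MMD between debiased N and R (computed
#' both under that temperature's feature weights and under uniform feature
#' weights).
#'
#' @param N,R raw or encoded `fwmrs_dataset`s (raw inputs are encoded
#'   internally with a shared map).
#' @param grid temperature grid.
#' @param cfg a [fwmrs_config()]; its temperature field is ignored.
#' @param n_runs number of seeded repetitions.
#' @param include_mrs add the uniform-feature-weight baseline row.
#' @return list with `summary` (one row per grid point) and `runs` (one row
#'   per run x grid point).
#' @export
temperature_sweep <- function(N, R, grid = c(0.001, 0.0025, 0.005, 0.01,
                                             0.025, 0.05, 0.1, 0.25, 0.5),
                              cfg = fwmrs_config(), n_runs = 20L,
                              include_mrs = TRUE) {
  stopifnot(length(grid) >= 1L, all(grid > 0))
  if (!N$encoded) {
    map <- fit_encoding(list(N, R))
    std <- cfg$classifier$family == "linear_svm"
    N <- apply_encoding(N, map, standardize = std)
    R <- apply_encoding(R, map, standardize = std)
  }
  p <- ncol(N$values)
  rows <- list()
  for (run in seq_len(n_runs)) {
    seed <- derive_seed(cfg$random_seed, 5000L + run)
    run_cfg <- cfg
    run_cfg$random_seed <- as.integer(seed %% 2147483647)
    clf <- train_domain_classifier(N, R, replace_seed(cfg$classifier, seed))
    imp <- estimate_importance(clf, method = cfg$importance_method,
                               n_background = cfg$n_background)
    settings <- c(as.list(grid),
                  if (include_mrs) list("mrs"))
    for (s in settings) {
      fw <- if (identical(s, "mrs")) {
        uniform_feature_weights(p, colnames(N$values))
      } else softmin_weights(imp, s)
      res <- run_fwmrs(N, R, run_cfg, feature_weights_override = fw)
      conv <- res$status == "converged"
      dropped <- if (conv) sum(res$sample_weights == 0) else NA_integer_
      sig <- heuristic_sigma(rbind(N$values, R$values))
      mmd_fw <- if (conv) weighted_mmd(N$values, R$values,
                                       w_X = as.numeric(res$sample_weights),
                                       w_f = as.numeric(fw), sigma = sig)
                else NA_real_
      mmd_unif <- if (conv) weighted_mmd(N$values, R$values,
                                         w_X = as.numeric(res$sample_weights),
                                         sigma = sig)
                  else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        run = run,
        temperature = if (identical(s, "mrs")) NA_real_ else s,
        setting = if (identical(s, "mrs")) "mrs" else sprintf("t=%g", s),
        status = res$status, n_dropped = dropped,
        final_auroc = if (conv) utils::tail(res$trace$mean_auroc, 1L)
                      else NA_real_,
        mmd_feature_weighted = mmd_fw, mmd_uniform = mmd_unif,
        stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  sum_rows <- lapply(split(runs, runs$setting), function(r) {
    data.frame(setting = r$setting[1L], temperature = r$temperature[1L],
               n_runs = nrow(r),
               n_infeasible = sum(r$status != "converged"),
               dropped_mean = mean(r$n_dropped, na.rm = TRUE),
               dropped_sd = stats::sd(r$n_dropped, na.rm = TRUE),
               mmd_mean = mean(r$mmd_uniform, na.rm = TRUE),
               mmd_sd = stats::sd(r$mmd_uniform, na.rm = TRUE),
               mmd_fw_mean = mean(r$mmd_feature_weighted, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, sum_rows)
  summary <- summary[order(is.na(summary$temperature), -summary$temperature,
                           na.last = FALSE), ]
  rownames(summary) <- NULL
  list(summary = summary, runs = runs)
}

replace_seed <- function(spec, seed) {
  spec$random_seed <- as.integer(seed %% 2147483647)
  spec
}
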