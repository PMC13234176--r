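#' Domain classifier specification
#'
#' The domain classifier distinguishes representative from non-representative
#' rows; its per-feature importances quantify how biased each feature is.
#' Two families are supported: a probability random forest (flexible,
#' detects non-linear bias) and an l2-regularized linear SVM (fast, detects
#' linear bias only).
#'
#' @param family `"random_forest"` or `"linear_svm"`.
#' @param n_trees number of trees for the forest family (default 200).
#' @param min_weight_fraction_leaf minimum fraction of the training weight a
#'   leaf must carry, in `[0, 0.5)`. Mapped to a minimum node size of
#'   `max(1, ceiling(fraction * n_train))`.
#' @param C SVM regularization strength (inverse penalty), `> 0`.
#' @param random_seed integer seed controlling all randomized steps.
#' @return object of class `fwmrs_classifier_spec`.
#' @export
domain_classifier_spec <- function(family = c("random_forest", "linear_svm"),
                                   n_trees = 200L,
                                   min_weight_fraction_leaf = 0.01,
                                   C = 1,
                                   random_seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_trees >= 1L, C > 0,
            min_weight_fraction_leaf >= 0, min_weight_fraction_leaf < 0.5)
  structure(
    list(family = family, n_trees = as.integer(n_trees),
         min_weight_fraction_leaf = min_weight_fraction_leaf,
         C = C, random_seed = as.integer(random_seed)),
    class = "fwmrs_classifier_spec"
  )
}

pooled_domain_matrix <- function(N, R) {
  stopifnot(inherits(N, "fwmrs_dataset"), inherits(R, "fwmrs_dataset"))
  if (!N$encoded || !R$encoded) {
    stop("N and R must be encoded into the shared numeric space first")
  }
  if (!identical(colnames(N$values), colnames(R$values))) {
    stop("schema mismatch: N and R do not share the encoded space")
  }
  if (nrow(N$values) == 0L) stop("N is empty")
  if (nrow(R$values) == 0L) stop("R is empty")
  list(X = rbind(N$values, R$values),
       y = c(rep(0L, nrow(N$values)), rep(1L, nrow(R$values))))
}

#' Train the unweighted domain classifier
#'
#' Trains a probabilistic classifier to distinguish the representative rows
#' (label 1) from the non-representative rows (label 0), with uniform sample
#' and feature weights. Its score for a row is the estimated probability of
#' being representative.
#'
#' @param N encoded non-representative `fwmrs_dataset`.
#' @param R encoded representative `fwmrs_dataset` in the same space. For the
#'   `linear_svm` family both must be standardized.
#' @param spec a [domain_classifier_spec()].
#' @return object of class `fwmrs_domain_classifier` with the fitted model
#'   and the pooled training matrix and labels.
#' @export
train_domain_classifier <- function(N, R, spec = domain_classifier_spec()) {
  stopifnot(inherits(spec, "fwmrs_classifier_spec"))
  pooled <- pooled_domain_matrix(N, R)
  p <- ncol(pooled$X)
  model <- if (spec$family == "random_forest") {
    fit_weighted_forest(
      pooled$X, pooled$y,
      cfg = weighted_forest_config(
        n_trees = spec$n_trees,
        min_weight_fraction_leaf = spec$min_weight_fraction_leaf,
        random_seed = spec$random_seed))
  } else {
    fit_weighted_linear_svm(
      pooled$X, pooled$y,
      cfg = weighted_svm_config(C = spec$C, random_seed = spec$random_seed))
  }
  structure(
    list(model = model, spec = spec, X = pooled$X, y = pooled$y),
    class = "fwmrs_domain_classifier"
  )
}

#' @export
predict.fwmrs_domain_classifier <- function(object, newdata, ...) {
  predict(object$model, newdata)
}

#' Interventional tree Shapley attributions for a weighted forest
#'
#' Exact per-tree Shapley values of the class-1 probability, with feature
#' removal realized interventionally: absent features take the values of a
#' background row, and attributions are averaged over the background set.
#'
#' @param forest a `fwmrs_weighted_forest`.
#' @param X foreground rows (numeric matrix in the forest's feature space).
#' @param background background rows; defaults to `X`.
#' @return matrix of attributions, `nrow(X)` by `ncol(X)`; rows sum to
#'   `f(x) - mean(f(background))`.
#' @export
tree_shapley <- function(forest, X, background = X) {
  stopifnot(inherits(forest, "fwmrs_weighted_forest"))
  arr <- forest$arrays
  phi <- tree_shap_interventional_cpp(arr$roots, arr$left, arr$right,
                                      arr$feat, arr$thresh, arr$value,
                                      X, background)
  colnames(phi) <- colnames(X)
  phi
}

#' Per-feature importances of a domain classifier
#'
#' Reduces row-level attributions to a global importance per encoded column:
#' the mean absolute Shapley attribution over the pooled rows, sum-normalized.
#' The tree family uses exact interventional tree Shapley against a seeded
#' background subsample of the pooled rows; the linear family uses Linear
#' SHAP, `beta_j * (x_ij - mean_j)` over a background mean. A permutation
#' fallback (mean AUROC drop over `n_shuffles` column shuffles) is available
#' for large inputs where Shapley attribution is too expensive.
#'
#' @param classifier a `fwmrs_domain_classifier`.
#' @param X rows to attribute over; defaults to the pooled training matrix.
#' @param method `"shapley"` (family-appropriate SHAP) or `"permutation"`.
#' @param n_background maximum number of background rows for interventional
#'   perturbation (seeded subsample of `X`).
#' @param n_shuffles shuffles per column for the permutation method.
#' @param aggregate optional encoded-column grouping (from
#'   [encoding_groups()]): member-column importances of each original feature
#'   are summed and shared equally back to its encoded columns, so a one-hot
#'   categorical is weighted as one feature.
#' @return object of class `fwmrs_importance`: nonnegative vector over
#'   encoded columns summing to 1, with attribute `source`.
#' @export
estimate_importance <- function(classifier, X = NULL,
                                method = c("shapley", "permutation"),
                                n_background = 100L, n_shuffles = 5L,
                                aggregate = NULL) {
  stopifnot(inherits(classifier, "fwmrs_domain_classifier"))
  method <- match.arg(method)
  if (is.null(X)) X <- classifier$X
  seed <- classifier$spec$random_seed
  if (method == "permutation") {
    imp <- permutation_importance(classifier, X, classifier$y,
                                  n_shuffles, seed)
    src <- "permutation"
  } else if (classifier$spec$family == "random_forest") {
    bg <- X
    if (nrow(bg) > n_background) {
      idx <- with_local_seed(derive_seed(seed, 7L),
                            sample.int(nrow(bg), n_background))
      bg <- bg[idx, , drop = FALSE]
    }
    phi <- tree_shapley(classifier$model, X, bg)
    imp <- colMeans(abs(phi))
    src <- "tree_shapley"
  } else {
    beta <- classifier$model$beta_raw # coefficients on the input scale
    ctr <- colMeans(X)
    imp <- abs(beta) * colMeans(abs(sweep(X, 2L, ctr, "-")))
    src <- "linear_shapley"
  }
  importance_vector(imp, source = src, aggregate = aggregate,
                    names = colnames(X))
}

importance_vector <- function(imp, source, aggregate = NULL, names = NULL) {
  imp[imp < 0] <- 0
  if (!is.null(aggregate)) {
    for (grp in aggregate) {
      if (length(grp) > 1L) imp[grp] <- sum(imp[grp]) / length(grp)
    }
  }
  tot <- sum(imp)
  if (!is.finite(tot) || tot <= 0) {
    warning("all-zero feature importances; falling back to the uniform vector")
    imp <- rep(1 / length(imp), length(imp))
  } else {
    imp <- imp / tot
  }
  if (!is.null(names)) names(imp) <- names
  structure(imp, class = "fwmrs_importance", source = source)
}

permutation_importance <- function(classifier, X, y, n_shuffles, seed) {
  base_scores <- predict(classifier, X)
  base_auc <- auroc(base_scores, y)
  p <- ncol(X)
  drops <- numeric(p)
  for (j in seq_len(p)) {
    accum <- 0
    for (s in seq_len(n_shuffles)) {
      Xp <- X
      perm <- with_local_seed(derive_seed(seed, 1000L + j * 17L + s),
                             sample.int(nrow(X)))
      Xp[, j] <- Xp[perm, j]
      accum <- accum + (base_auc - auroc(predict(classifier, Xp), y))
    }
    drops[j] <- accum / n_shuffles
  }
  drops
}

#' Softmin transformation of importances into feature weights
#'
#' `w_i = exp(-I_i / t) / sum_j exp(-I_j / t)`, computed with max-shift
#' stabilization. Highly important (i.e. highly biased) features receive low
#' weight. Low temperatures concentrate the weight on the least biased
#' feature; as `t -> Inf` the weights approach uniform.
#'
#' @param I numeric importance vector (any nonnegative scale; importances
#'   from [estimate_importance()] are already sum-normalized).
#' @param t positive temperature.
#' @return a [feature_weights()] simplex vector.
#' @export
softmin_weights <- function(I, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("temperature t must be a single positive number")
  }
  if (!is.numeric(I) || length(I) == 0L || any(!is.finite(I))) {
    stop("importances must be a finite numeric vector")
  }
  z <- -as.numeric(I) / t
  z <- z - max(z)
  w <- exp(z)
  w <- w / sum(w)
  if (!is.null(names(I))) names(w) <- names(I)
  feature_weights(w, temperature = t)
}
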