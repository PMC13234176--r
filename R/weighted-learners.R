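#' Configuration for the sample- and feature-weighted random forest
#'
#' @param n_trees number of trees.
#' @param min_weight_fraction_leaf minimum fraction of training weight per
#'   leaf, in `[0, 0.5)`; mapped to `min.node.size = max(1, ceiling(fraction
#'   * n_train))`.
#' @param candidate_features_per_split number of candidate features drawn at
#'   each split (`mtry`); defaults to `ceiling(sqrt(p))`, capped at the
#'   number of positive-weight features.
#' @param random_seed integer seed.
#' @return object of class `fwmrs_forest_config`.
#' @export
weighted_forest_config <- function(n_trees = 200L,
                                   min_weight_fraction_leaf = 0.01,
                                   candidate_features_per_split = NULL,
                                   random_seed = 1L) {
  stopifnot(n_trees >= 1L,
            min_weight_fraction_leaf >= 0, min_weight_fraction_leaf < 0.5)
  structure(
    list(n_trees = as.integer(n_trees),
         min_weight_fraction_leaf = min_weight_fraction_leaf,
         candidate_features_per_split = candidate_features_per_split,
         random_seed = as.integer(random_seed)),
    class = "fwmrs_forest_config"
  )
}

#' Configuration for the weighted linear SVM
#' @param C positive regularization strength (larger = less regularization).
#' @param random_seed integer seed (the fit itself is deterministic; the seed
#'   feeds downstream consumers).
#' @return object of class `fwmrs_svm_config`.
#' @export
weighted_svm_config <- function(C = 1, random_seed = 1L) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  structure(list(C = C, random_seed = as.integer(random_seed)),
            class = "fwmrs_svm_config")
}

check_xy <- function(X, y) {
  stopifnot(is.matrix(X), is.numeric(X))
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  y
}

#' Fit a feature- and sample-weighted random forest
#'
#' A probability forest of CART-style trees in which every split draws its
#' `candidate_features_per_split` candidate features *with replacement*
#' with probability proportional to the feature weights (duplicates
#' collapse) and takes the best weighted-Gini cut among them. Uniform
#' weights recover ordinary random-forest candidate sampling; sharply
#' peaked weights collapse the candidate sets onto the highest-weight
#' features — a soft feature selection — and zero-weight features are
#' never used. Rows with sample weight zero are excluded from training;
#' positive sample weights enter impurity, leaf values, and the
#' minimum-leaf-weight constraint. Fits are bit-reproducible given the
#' seed.
#'
#' @param X numeric feature matrix (unstandardized encodings are fine; trees
#'   are scale-invariant).
#' @param y binary 0/1 response.
#' @param sample_w optional nonnegative per-row weights (default all 1).
#' @param feature_w simplex feature weights, or `NULL` for the uniform
#'   (unweighted) forest.
#' @param cfg a [weighted_forest_config()].
#' @return object of class `fwmrs_weighted_forest`; `predict()` returns the
#'   estimated probability of class 1.
#' @export
fit_weighted_forest <- function(X, y, sample_w = NULL, feature_w = NULL,
                                cfg = weighted_forest_config()) {
  stopifnot(inherits(cfg, "fwmrs_forest_config"))
  y <- check_xy(X, y)
  p <- ncol(X)
  if (is.null(sample_w)) sample_w <- rep(1, nrow(X))
  if (length(sample_w) != nrow(X)) stop("sample weights do not match rows")
  if (all(sample_w == 0)) stop("all sample weights are zero")
  if (!is.null(feature_w)) {
    if (length(feature_w) != p) stop("feature weights do not match columns")
    if (all(feature_w == 0)) stop("all feature weights are zero")
    fw <- as.numeric(feature_w)
  } else {
    fw <- rep(1 / p, p)
  }
  active <- which(sample_w > 0)
  ya <- y[active]
  if (length(unique(ya)) < 2L) stop("need both classes among positive-weight rows")
  mtry <- cfg$candidate_features_per_split %||% ceiling(sqrt(p))
  arrays <- weighted_forest_fit_cpp(
    X[active, , drop = FALSE], ya, sample_w[active], fw,
    cfg$n_trees, as.integer(mtry), cfg$min_weight_fraction_leaf,
    as.integer(cfg$random_seed %% 2147483647))
  structure(
    list(arrays = arrays, feature_names = colnames(X),
         feature_w = fw, cfg = cfg),
    class = "fwmrs_weighted_forest"
  )
}

#' @export
predict.fwmrs_weighted_forest <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata),
            ncol(newdata) == length(object$feature_names))
  a <- object$arrays
  flat_forest_predict_cpp(a$roots, a$left, a$right, a$feat, a$thresh,
                          a$value, newdata)
}

#' Split-variable usage counts of a fitted weighted forest
#' @param forest a `fwmrs_weighted_forest`.
#' @return named integer vector: number of splits using each feature.
#' @export
forest_split_counts <- function(forest) {
  stopifnot(inherits(forest, "fwmrs_weighted_forest"))
  f <- forest$arrays$feat
  counts <- tabulate(f[f >= 0L] + 1L, nbins = length(forest$feature_names))
  names(counts) <- forest$feature_names
  counts
}

#' Fit a feature- and sample-weighted linear SVM
#'
#' Feature weights scale the input columns (`X %*% diag(w_f)`), modifying
#' each feature's influence on the margin; sample weights multiply each
#' row's contribution to the (squared-hinge) loss. The objective
#' `0.5 ||beta||^2 + C * sum_i w_i * max(0, 1 - y_i f(x_i))^2`
#' is minimized with L-BFGS-B; probabilities come from a Platt-style
#' sigmoid calibrated on the training decision values (monotone, so drop
#' rankings are unaffected by the calibration).
#'
#' @param X standardized numeric feature matrix.
#' @param y binary 0/1 response.
#' @param sample_w optional nonnegative per-row weights.
#' @param feature_w optional simplex feature weights.
#' @param cfg a [weighted_svm_config()].
#' @return object of class `fwmrs_weighted_svm`; `predict()` returns
#'   calibrated probabilities of class 1, `decision_values()` the raw margin.
#' @export
fit_weighted_linear_svm <- function(X, y, sample_w = NULL, feature_w = NULL,
                                    cfg = weighted_svm_config()) {
  stopifnot(inherits(cfg, "fwmrs_svm_config"))
  y <- check_xy(X, y)
  p <- ncol(X)
  if (is.null(sample_w)) sample_w <- rep(1, nrow(X))
  if (all(sample_w == 0)) stop("all sample weights are zero")
  if (is.null(feature_w)) feature_w <- rep(1, p) # unscaled
  active <- which(sample_w > 0)
  ya <- ifelse(y[active] == 1L, 1, -1)
  if (length(unique(ya)) < 2L) stop("need both classes among positive-weight rows")
  wa <- sample_w[active]
  Xs <- sweep(X[active, , drop = FALSE], 2L, as.numeric(feature_w), "*")
  C <- cfg$C
  obj <- function(theta) {
    b <- theta[1L]; beta <- theta[-1L]
    m <- 1 - ya * (drop(Xs %*% beta) + b)
    viol <- pmax(m, 0)
    0.5 * sum(beta^2) + C * sum(wa * viol^2)
  }
  grad <- function(theta) {
    b <- theta[1L]; beta <- theta[-1L]
    m <- 1 - ya * (drop(Xs %*% beta) + b)
    act <- m > 0
    coef <- numeric(length(ya))
    coef[act] <- -2 * C * wa[act] * ya[act] * m[act]
    c(sum(coef), beta + drop(crossprod(Xs, coef)))
  }
  opt <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500L, factr = 1e7))
  b <- opt$par[1L]; beta <- opt$par[-1L]
  dv <- drop(Xs %*% beta) + b
  platt <- fit_platt(dv, (ya + 1) / 2, wa)
  structure(
    list(beta = beta, intercept = b, feature_w = as.numeric(feature_w),
         beta_raw = beta * as.numeric(feature_w), # coefficients on input scale
         platt = platt, cfg = cfg, objective = opt$value,
         feature_names = colnames(X)),
    class = "fwmrs_weighted_svm"
  )
}

fit_platt <- function(dv, y01, w) {
  # degenerate case: perfectly constant decision values
  if (stats::var(dv) == 0) return(c(a = 0, b = 0))
  fit <- suppressWarnings(
    stats::glm(y01 ~ dv, family = stats::binomial(), weights = w)
  )
  co <- stats::coef(fit)
  c(a = unname(co[2L]), b = unname(co[1L]))
}

#' Raw decision values of a weighted linear SVM
#' @param object a `fwmrs_weighted_svm`.
#' @param newdata numeric matrix on the same (standardized) input scale.
#' @return numeric vector of margins.
#' @export
decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "fwmrs_weighted_svm"))
  Xs <- sweep(newdata, 2L, object$feature_w, "*")
  drop(Xs %*% object$beta) + object$intercept
}

#' @export
predict.fwmrs_weighted_svm <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  1 / (1 + exp(-(object$platt["a"] * dv + object$platt["b"])))
}

#' Sample-weighted area under the ROC curve
#'
#' The weighted probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counted one half. Rows with zero sample
#' weight are ignored.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary 0/1 labels.
#' @param sample_w optional nonnegative weights.
#' @return AUROC in `[0, 1]`, or `NA_real_` when only one class has positive
#'   weight (the caller is expected to skip such folds).
#' @export
auroc <- function(scores, labels, sample_w = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (is.null(sample_w)) sample_w <- rep(1, length(scores))
  keep <- sample_w > 0
  s <- scores[keep]; y <- labels[keep]; w <- sample_w[keep]
  wpos <- sum(w[y == 1L]); wneg <- sum(w[y == 0L])
  if (wpos == 0 || wneg == 0) return(NA_real_)
  o <- order(s)
  s <- s[o]; y <- y[o]; w <- w[o]
  grp <- cumsum(c(1L, as.integer(diff(s) != 0)))
  wp <- rowsum(w * (y == 1L), grp)
  wn <- rowsum(w * (y == 0L), grp)
  cum_before <- cumsum(wn) - wn
  sum(wp * (cum_before + 0.5 * wn)) / (wpos * wneg)
}
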