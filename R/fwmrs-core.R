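#' Configuration for the FW-MRS debiasing loop
#'
#' @param temperature positive softmin temperature `t`. Low values
#'   concentrate feature weight on the least biased features (fewer samples
#'   dropped); high values approach uniform weighting, i.e. plain MRS. The
#'   default 0.25 is a conservative, mildly weighted setting; lower it
#'   deliberately (or tune over the 0.001-0.5 grid) when sample retention
#'   matters more than downstream accuracy.
#' @param k number of cross-validation folds per iteration (`>= 2`).
#' @param d number of samples dropped per iteration (`>= 1`).
#' @param classifier a [domain_classifier_spec()]; its family is used both
#'   for the importance-bearing unweighted classifier and for the weighted
#'   per-fold classifiers.
#' @param auroc_stop_threshold stop once the fold-mean AUROC is `<=` this
#'   value (default 0.5, "no better than random guessing"). Exposed for
#'   testing; not intended as a user-facing tuning knob.
#' @param random_seed master seed for fold shuffles and classifier fits.
#' @param max_iterations cap on loop iterations; defaults to the attrition
#'   bound `floor((n - 1) / d) + 1`, which the loop can never exceed, so the
#'   cap only guards against contract violations.
#' @param importance_method passed to [estimate_importance()].
#' @param n_background background subsample cap for interventional Shapley.
#' @return object of class `fwmrs_config`.
#' @export
fwmrs_config <- function(temperature = 0.25, k = 5L, d = 1L,
                         classifier = domain_classifier_spec(),
                         auroc_stop_threshold = 0.5,
                         random_seed = 1L,
                         max_iterations = NULL,
                         importance_method = "shapley",
                         n_background = 100L) {
  stopifnot(k >= 2L, d >= 1L, temperature > 0,
            inherits(classifier, "fwmrs_classifier_spec"))
  structure(
    list(temperature = temperature, k = as.integer(k), d = as.integer(d),
         classifier = classifier,
         auroc_stop_threshold = auroc_stop_threshold,
         random_seed = as.integer(random_seed),
         max_iterations = max_iterations,
         importance_method = importance_method,
         n_background = as.integer(n_background)),
    class = "fwmrs_config"
  )
}

new_debias_result <- function(status, sample_w, feature_w, trace, method) {
  structure(
    list(status = status,
         sample_weights = sample_w,
         feature_weights = feature_w,
         trace = trace,
         method = method),
    class = "fwmrs_debias_result"
  )
}

#' @export
print.fwmrs_debias_result <- function(x, ...) {
  cat(sprintf("<fwmrs_debias_result> method = %s, status = %s\n",
              x$method, x$status))
  if (x$status == "converged") {
    n <- length(x$sample_weights)
    cat(sprintf("  %d / %d samples retained (%.1f%% dropped); final mean AUROC %.3f after %d iteration(s)\n",
                sum(x$sample_weights > 0), n,
                100 * mean(x$sample_weights == 0),
                utils::tail(x$trace$mean_auroc, 1L), nrow(x$trace)))
  } else {
    cat("  bias could not be sufficiently mitigated; no weights returned\n")
  }
  invisible(x)
}

fit_fold_classifier <- function(X, y, feature_w, spec, seed) {
  if (spec$family == "random_forest") {
    fit_weighted_forest(
      X, y, feature_w = feature_w,
      cfg = weighted_forest_config(
        n_trees = spec$n_trees,
        min_weight_fraction_leaf = spec$min_weight_fraction_leaf,
        random_seed = seed))
  } else {
    fit_weighted_linear_svm(
      X, y, feature_w = feature_w,
      cfg = weighted_svm_config(C = spec$C, random_seed = seed))
  }
}

#' One PU-learning cross-validation round of the debiasing loop
#'
#' Pools the active non-representative rows (treated as unlabeled, labeled
#' negative) with the representative rows (positive), splits the pool into
#' `k` folds stratified by source with a seeded shuffle, trains the weighted
#' domain classifier on each k-1-fold training set, and scores the held-out
#' fold. Returns the fold-mean AUROC (the stopping statistic) and the
#' out-of-fold representativeness score of every active N row (the drop
#' ranking). Folds whose hold-out lacks one source are skipped from the
#' mean.
#'
#' @param N_active numeric matrix of active non-representative rows.
#' @param R_mat numeric matrix of representative rows in the same space.
#' @param feature_w simplex feature weights for the weighted classifier.
#' @param cfg a [fwmrs_config()].
#' @param seed fold-shuffle seed (defaults to `cfg$random_seed`).
#' @return list with `mean_auroc`, `oof_scores` (per active N row), and
#'   `fold_auroc`.
#' @export
cv_round <- function(N_active, R_mat, feature_w, cfg, seed = NULL) {
  stopifnot(is.matrix(N_active), is.matrix(R_mat),
            ncol(N_active) == ncol(R_mat))
  if (nrow(N_active) == 0L) stop("no active non-representative rows")
  if (nrow(R_mat) == 0L) stop("representative set is empty")
  seed <- seed %||% cfg$random_seed
  k <- cfg$k
  nN <- nrow(N_active); nR <- nrow(R_mat)
  X <- rbind(N_active, R_mat)
  y <- c(rep(0L, nN), rep(1L, nR))
  # stratified-by-source fold assignment with a seeded shuffle
  foldsN <- with_local_seed(derive_seed(seed, 1L),
                           sample(rep_len(seq_len(k), nN)))
  foldsR <- with_local_seed(derive_seed(seed, 2L),
                           sample(rep_len(seq_len(k), nR)))
  folds <- c(foldsN, foldsR)
  oof <- rep(NA_real_, nN)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    train <- which(folds != f)
    ytr <- y[train]
    if (length(unique(ytr)) < 2L) next
    clf <- fit_fold_classifier(X[train, , drop = FALSE], ytr, feature_w,
                               cfg$classifier, derive_seed(seed, 100L + f))
    sc <- predict(clf, X[hold, , drop = FALSE])
    fold_auc[f] <- auroc(sc, y[hold])
    isN <- hold <= nN
    oof[hold[isN]] <- sc[isN]
  }
  if (all(is.na(fold_auc))) {
    stop("every fold lacked one source; cannot evaluate the stopping rule")
  }
  list(mean_auroc = mean(fold_auc, na.rm = TRUE),
       oof_scores = oof, fold_auroc = fold_auc)
}

#' Run feature-weighted maximum representative subsampling
#'
#' Implements the full iterative loop: all sample weights start at 1; an
#' unweighted domain classifier trained on N (label 0) vs R (label 1) yields
#' per-feature importances, which softmin at temperature `t` converts to
#' feature weights; then, while the weighted domain classifier can still
#' distinguish the active rows of N from R (fold-mean AUROC above the
#' stopping threshold), the `d` active rows scored most confidently
#' non-representative out-of-fold have their weights set to zero. If fewer
#' than `d + 1` active rows remain before the threshold is reached, the bias
#' cannot be sufficiently mitigated and no weights are returned.
#'
#' @param N encoded non-representative `fwmrs_dataset`.
#' @param R encoded representative `fwmrs_dataset` in the same space (for the
#'   `linear_svm` family both must be standardized).
#' @param cfg a [fwmrs_config()].
#' @param feature_weights_override optional `fwmrs_feature_weights` used
#'   instead of the softmin-of-importances computation; plain MRS is the
#'   special case of the exact uniform vector (see [run_mrs()]).
#' @return a `fwmrs_debias_result`: `status` (`"converged"` or
#'   `"infeasible"`), binary `sample_weights` over N, `feature_weights`, and
#'   a per-iteration `trace` (iteration, mean AUROC, dropped row indices,
#'   cumulative dropped count). On infeasible exits both weight fields are
#'   `NULL`.
#' @export
run_fwmrs <- function(N, R, cfg = fwmrs_config(),
                      feature_weights_override = NULL) {
  stopifnot(inherits(cfg, "fwmrs_config"))
  pooled <- pooled_domain_matrix(N, R) # validates shared encoded space
  n <- nrow(N$values)
  if (n <= cfg$d) {
    return(new_debias_result("infeasible", NULL, NULL,
                             empty_trace(), method_name(cfg)))
  }
  if (is.null(feature_weights_override)) {
    clf <- train_domain_classifier(N, R, cfg$classifier)
    imp <- estimate_importance(clf, method = cfg$importance_method,
                               n_background = cfg$n_background)
    fw <- softmin_weights(imp, cfg$temperature)
  } else {
    stopifnot(inherits(feature_weights_override, "fwmrs_feature_weights"))
    if (length(feature_weights_override) != ncol(N$values)) {
      stop("feature weight override does not match the encoded space")
    }
    fw <- feature_weights_override
  }
  w <- rep(1, n)
  max_iter <- cfg$max_iterations %||% (floor((n - 1) / cfg$d) + 1L)
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("max_iterations exceeded")
    active <- which(w > 0)
    if (length(active) <= cfg$d) {
      return(new_debias_result("infeasible", NULL, NULL,
                               bind_trace(trace), method_name(cfg)))
    }
    cvr <- cv_round(N$values[active, , drop = FALSE], R$values, fw, cfg,
                    seed = derive_seed(cfg$random_seed, iter))
    if (cvr$mean_auroc <= cfg$auroc_stop_threshold) {
      trace[[iter]] <- data.frame(iteration = iter,
                                  mean_auroc = cvr$mean_auroc,
                                  n_dropped = 0L,
                                  n_dropped_total = sum(w == 0))
      return(new_debias_result("converged", sample_weights(w), fw,
                               bind_trace(trace), method_name(cfg)))
    }
    # drop the d lowest out-of-fold representativeness scores;
    # ties broken by ascending row index
    ord <- order(cvr$oof_scores, active)
    drop_idx <- active[ord[seq_len(cfg$d)]]
    w[drop_idx] <- 0
    trace[[iter]] <- data.frame(iteration = iter,
                                mean_auroc = cvr$mean_auroc,
                                n_dropped = cfg$d,
                                n_dropped_total = sum(w == 0),
                                dropped = I(list(drop_idx)))
  }
}

method_name <- function(cfg) {
  paste0("fwmrs_", if (cfg$classifier$family == "random_forest") "rf" else "svm")
}

empty_trace <- function() {
  data.frame(iteration = integer(0), mean_auroc = numeric(0),
             n_dropped = integer(0), n_dropped_total = integer(0))
}

bind_trace <- function(trace) {
  if (length(trace) == 0L) return(empty_trace())
  dropped <- lapply(trace, function(r) if ("dropped" %in% names(r))
    r$dropped[[1L]] else integer(0))
  out <- do.call(rbind, lapply(trace, function(r)
    r[, c("iteration", "mean_auroc", "n_dropped", "n_dropped_total")]))
  out$dropped <- I(dropped)
  rownames(out) <- NULL
  out
}

#' Ordered sequence of dropped row indices of a debiasing run
#' @param result a `fwmrs_debias_result`.
#' @return integer vector of row indices of N in drop order.
#' @export
drop_sequence <- function(result) {
  stopifnot(inherits(result, "fwmrs_debias_result"))
  unlist(result$trace$dropped, use.names = FALSE)
}
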