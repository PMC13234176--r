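DEBIAS_METHODS <- c("fwmrs_rf", "fwmrs_svm", "mrs", "kmm", "psa", "uniform")

normalize_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  if (!m %in% DEBIAS_METHODS) {
    stop(sprintf("unknown method '%s'; valid methods: %s", method,
                 paste(DEBIAS_METHODS, collapse = ", ")))
  }
  m
}

#' Debias a non-representative dataset against a representative reference
#'
#' End-to-end convenience wrapper: fits a shared encoding on the two raw
#' datasets, encodes them (standardized for the kernel/linear methods,
#' raw encodings for the tree methods), and dispatches to the selected
#' debiasing method.
#'
#' @param N raw non-representative `fwmrs_dataset` (see [load_dataset()]).
#' @param R raw representative `fwmrs_dataset` with the same schema.
#' @param method one of `"fwmrs_rf"`, `"fwmrs_svm"`, `"mrs"`, `"kmm"`,
#'   `"psa"`, `"uniform"` (hyphens accepted).
#' @param temperature softmin temperature for the FW-MRS variants.
#' @param k,d cross-validation folds and drops per iteration of the
#'   subsampling loop.
#' @param C regularization for the SVM variant and PSA.
#' @param n_trees domain-classifier forest size.
#' @param min_weight_fraction_leaf domain-classifier leaf regularization.
#' @param seed master random seed.
#' @return a `fwmrs_debias_result`; for KMM/PSA/uniform the trace is empty,
#'   the sample weights are continuous (KMM/PSA) or all 1 (uniform), and
#'   the feature weights are uniform. The fitted encoding is attached as
#'   attribute `encoding`.
#' @export
debias <- function(N, R, method = "fwmrs_rf", temperature = 0.25,
                   k = 5L, d = 1L, C = 1, n_trees = 200L,
                   min_weight_fraction_leaf = 0.01, seed = 1L) {
  method <- normalize_method(method)
  stopifnot(inherits(N, "fwmrs_dataset"), inherits(R, "fwmrs_dataset"))
  map <- fit_encoding(list(N, R))
  needs_std <- method %in% c("fwmrs_svm", "kmm", "psa")
  Ne <- apply_encoding(N, map, standardize = needs_std)
  Re <- apply_encoding(R, map, standardize = needs_std)
  p <- ncol(Ne$values)
  res <- switch(
    method,
    fwmrs_rf = run_fwmrs(Ne, Re, fwmrs_config(
      temperature = temperature, k = k, d = d,
      classifier = domain_classifier_spec(
        "random_forest", n_trees = n_trees,
        min_weight_fraction_leaf = min_weight_fraction_leaf,
        random_seed = seed),
      random_seed = seed)),
    fwmrs_svm = run_fwmrs(Ne, Re, fwmrs_config(
      temperature = temperature, k = k, d = d,
      classifier = domain_classifier_spec("linear_svm", C = C,
                                          random_seed = seed),
      random_seed = seed)),
    mrs = run_mrs(Ne, Re, fwmrs_config(
      k = k, d = d,
      classifier = domain_classifier_spec(
        "random_forest", n_trees = n_trees,
        min_weight_fraction_leaf = min_weight_fraction_leaf,
        random_seed = seed),
      random_seed = seed)),
    kmm = new_debias_result(
      "converged", kmm_weights(Ne, Re),
      uniform_feature_weights(p, colnames(Ne$values)), empty_trace(), "kmm"),
    psa = new_debias_result(
      "converged", psa_weights(Ne, Re, C = C),
      uniform_feature_weights(p, colnames(Ne$values)), empty_trace(), "psa"),
    uniform = new_debias_result(
      "converged", uniform_weights(Ne),
      uniform_feature_weights(p, colnames(Ne$values)), empty_trace(),
      "uniform")
  )
  attr(res, "encoding") <- map
  res
}
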