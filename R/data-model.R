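#' @useDynLib fwmrs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict sd var
NULL

DATASET_ROLES <- c("nonrepresentative", "representative", "test")

#' Construct a tabular dataset with an optional binary outcome
#'
#' A `fwmrs_dataset` bundles a feature table (raw mixed-type columns before
#' encoding, a numeric matrix after [apply_encoding()]), an optional 0/1
#' outcome vector, and a role tag saying which side of the debiasing problem
#' the rows belong to: the non-representative sample `N`, the representative
#' reference `R`, or a held-out test set `T`.
#'
#' Missing values are a hard error: imputation would silently alter the very
#' distributions the debiasing methods compare.
#'
#' @param values data.frame (raw) or numeric matrix (encoded) of features.
#' @param role one of `"nonrepresentative"`, `"representative"`, `"test"`.
#' @param outcome optional integer/numeric vector of 0/1 outcomes, one per row.
#' @param encoded logical; `TRUE` when `values` is a numeric matrix in an
#'   encoded feature space.
#' @return An object of class `fwmrs_dataset` with elements `values`,
#'   `column_names`, `outcome`, `role`, `encoded`.
#' @export
fwmrs_dataset <- function(values, role, outcome = NULL, encoded = FALSE) {
  role <- match.arg(role, DATASET_ROLES)
  if (is.matrix(values)) {
    if (!is.numeric(values)) stop("matrix 'values' must be numeric")
  } else if (!is.data.frame(values)) {
    stop("'values' must be a data.frame or numeric matrix")
  }
  if (nrow(values) == 0L) stop("empty table: dataset has no rows")
  if (ncol(values) == 0L) stop("dataset has no feature columns")
  cn <- colnames(values)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn))) {
    stop("column names must be present, non-empty and unique")
  }
  check_no_missing(values)
  if (!is.null(outcome)) {
    outcome <- validate_outcome(outcome, nrow(values))
  }
  structure(
    list(values = values, column_names = cn, outcome = outcome,
         role = role, encoded = isTRUE(encoded)),
    class = "fwmrs_dataset"
  )
}

check_no_missing <- function(values) {
  if (is.matrix(values)) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("missing value at row %d, column %s",
                   bad[1L, 1L], colnames(values)[bad[1L, 2L]]))
    }
    return(invisible(NULL))
  }
  for (j in seq_along(values)) {
    col <- values[[j]]
    miss <- is.na(col) | (is.character(col) & !nzchar(trimws(col)))
    if (any(miss)) {
      stop(sprintf("missing value at row %d, column %s",
                   which(miss)[1L], colnames(values)[j]))
    }
  }
  invisible(NULL)
}

validate_outcome <- function(outcome, n) {
  if (length(outcome) != n) {
    stop(sprintf("outcome has %d entries but the table has %d rows",
                 length(outcome), n))
  }
  if (anyNA(outcome)) stop("outcome contains missing values")
  num <- suppressWarnings(as.numeric(as.character(outcome)))
  if (anyNA(num) || !all(num %in% c(0, 1))) {
    stop("outcome column is not binary: values must all be 0 or 1")
  }
  as.integer(num)
}

#' @export
print.fwmrs_dataset <- function(x, ...) {
  cat(sprintf("<fwmrs_dataset> %d rows x %d columns, role = %s%s%s\n",
              nrow(x$values), length(x$column_names), x$role,
              if (x$encoded) ", encoded" else "",
              if (!is.null(x$outcome)) sprintf(", outcome prevalence %.3f",
                                               mean(x$outcome)) else ""))
  invisible(x)
}

#' Number of rows in a dataset
#' @param ds a `fwmrs_dataset`.
#' @return integer row count.
#' @export
n_samples <- function(ds) {
  stopifnot(inherits(ds, "fwmrs_dataset"))
  nrow(ds$values)
}

#' Subset the rows of a dataset
#'
#' Keeps outcome alignment and all metadata.
#' @param ds a `fwmrs_dataset`.
#' @param idx integer row indices to keep.
#' @return a `fwmrs_dataset` with the selected rows.
#' @export
dataset_rows <- function(ds, idx) {
  stopifnot(inherits(ds, "fwmrs_dataset"))
  vals <- if (is.matrix(ds$values)) ds$values[idx, , drop = FALSE]
          else ds$values[idx, , drop = FALSE]
  out <- structure(
    list(values = vals, column_names = ds$column_names,
         outcome = if (!is.null(ds$outcome)) ds$outcome[idx] else NULL,
         role = ds$role, encoded = ds$encoded),
    class = "fwmrs_dataset"
  )
  out
}

#' Load a delimited text table as a dataset
#'
#' Reads a comma-separated UTF-8 table with one header row, validates it
#' (no missing/empty cells, unique column names), detects categorical
#' columns by non-numeric content, and optionally splits off a binary
#' outcome column.
#'
#' @param path path to the CSV file.
#' @param role dataset role tag, see [fwmrs_dataset()].
#' @param outcome_column optional name of a 0/1 outcome column; it is removed
#'   from the feature table and stored separately.
#' @param sep field separator, comma by default.
#' @return a raw (unencoded) `fwmrs_dataset`.
#' @export
load_dataset <- function(path, role, outcome_column = NULL, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          fileEncoding = "UTF-8", fill = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty table: %s", path))
  # coerce columns that are entirely numeric; everything else is categorical
  for (j in seq_along(df)) {
    col <- trimws(df[[j]])
    num <- suppressWarnings(as.numeric(col))
    df[[j]] <- if (!anyNA(num) && !any(!nzchar(col))) num else col
  }
  outcome <- NULL
  if (!is.null(outcome_column)) {
    if (!outcome_column %in% colnames(df)) {
      stop(sprintf("outcome column '%s' not found", outcome_column))
    }
    outcome <- df[[outcome_column]]
    df[[outcome_column]] <- NULL
    if (ncol(df) == 0L) stop("no feature columns remain after removing the outcome")
  }
  fwmrs_dataset(df, role = role, outcome = outcome)
}

#' Fit a shared one-hot + standardization encoding over several datasets
#'
#' All debiasing methods compare `N` and `R` in one numeric space, so the
#' encoding is fit on the union of the supplied datasets: categorical columns
#' are one-hot expanded over the union of their levels (levels sorted
#' lexicographically, original column order preserved) and z-score parameters
#' are computed on the pooled rows. Per-dataset centering would erase exactly
#' the distribution shifts the methods must detect.
#'
#' @param datasets list of raw `fwmrs_dataset` objects sharing a schema.
#' @return an object of class `fwmrs_encoding`: for every original feature the
#'   encoded column indices, and per encoded column a center and a strictly
#'   positive scale (constant columns get scale 1).
#' @export
fit_encoding <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  lapply(datasets, function(d) stopifnot(inherits(d, "fwmrs_dataset")))
  cn <- datasets[[1L]]$column_names
  for (d in datasets[-1L]) {
    if (!identical(d$column_names, cn)) {
      stop("schema mismatch: datasets do not share identical column names")
    }
    if (d$encoded) stop("fit_encoding expects raw (unencoded) datasets")
  }
  columns <- vector("list", length(cn))
  names(columns) <- cn
  enc_names <- character(0)
  for (j in seq_along(cn)) {
    pooled <- unlist(lapply(datasets, function(d) d$values[[j]]),
                     use.names = FALSE)
    if (is.numeric(pooled)) {
      columns[[j]] <- list(type = "numeric", levels = NULL)
      enc_names <- c(enc_names, cn[j])
    } else {
      lev <- sort(unique(as.character(pooled)))
      columns[[j]] <- list(type = "categorical", levels = lev)
      enc_names <- c(enc_names, paste0(cn[j], "=", lev))
    }
  }
  map <- structure(
    list(column_names = cn, columns = columns, encoded_names = enc_names,
         center = NULL, scale = NULL),
    class = "fwmrs_encoding"
  )
  pooled_mat <- do.call(rbind, lapply(datasets, function(d)
    encode_matrix(d, map)))
  ctr <- colMeans(pooled_mat)
  scl <- apply(pooled_mat, 2L, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  map$center <- ctr
  map$scale <- scl
  map
}

# raw dataset -> numeric matrix in the encoded space (no standardization)
encode_matrix <- function(dataset, map) {
  df <- dataset$values
  cols <- vector("list", length(map$column_names))
  for (j in seq_along(map$column_names)) {
    spec <- map$columns[[j]]
    col <- df[[j]]
    if (spec$type == "numeric") {
      if (!is.numeric(col)) {
        stop(sprintf("column '%s' was numeric at fit time but is not here",
                     map$column_names[j]))
      }
      cols[[j]] <- matrix(col, ncol = 1L)
    } else {
      col <- as.character(col)
      unseen <- setdiff(unique(col), spec$levels)
      if (length(unseen) > 0L) {
        stop(sprintf("unseen category level '%s' in column '%s'",
                     unseen[1L], map$column_names[j]))
      }
      onehot <- vapply(spec$levels, function(l) as.numeric(col == l),
                       numeric(length(col)))
      cols[[j]] <- matrix(onehot, nrow = length(col))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- map$encoded_names
  m
}

#' Map indices of encoded columns back to their original feature
#'
#' @param map a `fwmrs_encoding`.
#' @return named list: original feature -> integer vector of encoded columns.
#' @export
encoding_groups <- function(map) {
  stopifnot(inherits(map, "fwmrs_encoding"))
  sizes <- vapply(map$columns, function(s)
    if (s$type == "numeric") 1L else length(s$levels), integer(1))
  idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
  names(idx) <- map$column_names
  idx
}

#' Apply a fitted encoding to a dataset
#'
#' @param dataset raw `fwmrs_dataset` matching the schema the map was fit on.
#' @param map a `fwmrs_encoding` from [fit_encoding()].
#' @param standardize if `TRUE`, z-scores each encoded column with the pooled
#'   parameters stored in the map. Kernel and linear methods (SVM, KMM, MMD)
#'   need this; trees are scale-invariant and should receive raw encodings.
#' @return an encoded `fwmrs_dataset` whose `values` is a numeric matrix.
#' @export
apply_encoding <- function(dataset, map, standardize = FALSE) {
  stopifnot(inherits(dataset, "fwmrs_dataset"), inherits(map, "fwmrs_encoding"))
  if (dataset$encoded) stop("dataset is already encoded")
  if (!identical(dataset$column_names, map$column_names)) {
    stop("schema mismatch: dataset columns do not match the encoding map")
  }
  m <- encode_matrix(dataset, map)
  if (standardize) {
    m <- sweep(m, 2L, map$center, "-")
    m <- sweep(m, 2L, map$scale, "/")
  }
  fwmrs_dataset(m, role = dataset$role, outcome = dataset$outcome,
                encoded = TRUE)
}

#' Nonnegative per-sample weights
#'
#' In (FW-)MRS sample weights are binary: 1 for an active sample, exactly 0
#' for a dropped one. KMM and PSA produce continuous nonnegative weights.
#'
#' @param weights numeric vector, all entries `>= 0` and finite.
#' @return object of class `fwmrs_sample_weights` (a numeric vector).
#' @export
sample_weights <- function(weights) {
  if (!is.numeric(weights) || length(weights) == 0L) {
    stop("weights must be a non-empty numeric vector")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("sample weights must be finite and >= 0")
  }
  structure(as.numeric(weights), class = "fwmrs_sample_weights")
}

#' Simplex feature weights at a softmin temperature
#'
#' @param weights numeric vector over encoded columns; entries in `(0, 1]`
#'   summing to 1 (tolerance 1e-9).
#' @param temperature the positive softmin temperature that produced them
#'   (`NA` for externally supplied weights, e.g. the exact uniform vector).
#' @return object of class `fwmrs_feature_weights`.
#' @export
feature_weights <- function(weights, temperature = NA_real_) {
  if (!is.numeric(weights) || length(weights) == 0L) {
    stop("feature weights must be a non-empty numeric vector")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1)) {
    stop("feature weights must lie in [0, 1]")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("feature weights must sum to 1 (within 1e-9)")
  }
  if (!is.na(temperature) && temperature <= 0) stop("temperature must be > 0")
  out <- as.numeric(weights)
  names(out) <- names(weights)
  structure(out, class = "fwmrs_feature_weights", temperature = temperature)
}

#' Exactly uniform feature weights
#' @param p number of encoded columns.
#' @param names optional column names.
#' @return `fwmrs_feature_weights` with every entry `1/p`.
#' @export
uniform_feature_weights <- function(p, names = NULL) {
  w <- rep(1 / p, p)
  if (!is.null(names)) names(w) <- names
  feature_weights(w, temperature = NA_real_)
}

#' Write a weight vector as a two-column CSV
#' @param w numeric vector of weights (sample or feature weights).
#' @param path output file.
#' @param id_name name for the first column (`sample_index` or `feature_name`).
#' @param ids identifiers; defaults to `seq_along(w)`.
#' @export
write_weights_csv <- function(w, path, id_name = "sample_index", ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(w))) names(w) else seq_along(w)
  df <- data.frame(id = ids, weight = as.numeric(w))
  names(df)[1L] <- id_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
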