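#' Read a tabular regression dataset from CSV
#'
#' Loads a headed CSV file, designates one column as the outcome and
#' (optionally) one as observation weights, and returns the remaining columns
#' as the feature matrix.  Rows containing any missing value in a used column
#' are dropped with a message reporting the count.  Every column is treated as
#' numeric: categorical variables must already be numerically coded by the
#' caller (character columns are coerced with a warning; values that fail to
#' parse become missing and their rows are dropped).
#'
#' Weights are carried for *evaluation only* — [mspe()], [holdout_mspe()] and
#' [cv_mspe()] use them to weight squared errors; they play no role in
#' bootstrap sampling or split selection.
#'
#' @param path path to a CSV file with a header row.
#' @param outcome name of the outcome column.
#' @param weights optional name of a strictly positive weight column.
#' @return An object of class `"reg_dataset"`: a list with elements `x`
#'   (numeric feature matrix), `y` (outcome vector), `w` (weights, all 1 when
#'   no weight column is given), `feature_names`, `outcome_name`, `n`, `p`,
#'   and `n_dropped` (rows removed for missingness).
#' @seealso [write_regression_csv()], [check_schema()]
#' @export
read_regression_csv <- function(path, outcome, weights = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (!outcome %in% names(df)) {
    stopf("outcome column '%s' not present in %s", outcome, path)
  }
  if (!is.null(weights) && !weights %in% names(df)) {
    stopf("weight column '%s' not present in %s", weights, path)
  }
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      warning(sprintf("coercing non-numeric column '%s' to numeric", nm),
              call. = FALSE)
      df[[nm]] <- suppressWarnings(as.numeric(as.character(df[[nm]])))
    }
  }
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_regression_csv: dropped %d incomplete row%s",
                    n_dropped, if (n_dropped == 1) "" else "s"))
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stopf("no complete rows left after dropping missing values")
  y <- df[[outcome]]
  w <- if (is.null(weights)) rep(1, nrow(df)) else df[[weights]]
  if (any(w <= 0)) stopf("weights must be strictly positive")
  feat_cols <- setdiff(names(df), c(outcome, weights))
  if (length(feat_cols) == 0L) stopf("no feature columns remain")
  x <- as_feature_matrix(df[, feat_cols, drop = FALSE])
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(w))) {
    stopf("non-finite values present after loading")
  }
  new_reg_dataset(x, y, w, outcome, n_dropped)
}

new_reg_dataset <- function(x, y, w, outcome_name, n_dropped = 0L) {
  structure(list(x = x, y = as.numeric(y), w = as.numeric(w),
                 feature_names = colnames(x), outcome_name = outcome_name,
                 n = nrow(x), p = ncol(x), n_dropped = as.integer(n_dropped)),
            class = "reg_dataset")
}

#' @export
print.reg_dataset <- function(x, ...) {
  cat(sprintf("Regression dataset: %d observations, %d features\n", x$n, x$p))
  cat(sprintf("  outcome: %s  (weights %s)\n", x$outcome_name,
              if (all(x$w == 1)) "uniform" else "supplied"))
  if (x$n_dropped > 0) cat(sprintf("  %d incomplete rows dropped at load\n", x$n_dropped))
  invisible(x)
}

#' Write a regression dataset to CSV
#'
#' Inverse of [read_regression_csv()]: writes outcome, features and (when not
#' uniform) weights in the same dialect, so generated fixtures round-trip.
#'
#' @param dataset a `"reg_dataset"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regression_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "reg_dataset"))
  df <- as.data.frame(dataset$x)
  df[[dataset$outcome_name]] <- dataset$y
  if (!all(dataset$w == 1)) df[[".weight"]] <- dataset$w
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dispersion summary of an outcome vector
#'
#' Computes the dataset-level statistics the dispersion stopping rules are
#' anchored to: the population variance (divisor `n`), the range
#' (max - min), and the intercentile range `[X, 100 - X]` for each requested
#' centile, using linear-interpolation ("type 7") percentiles.
#'
#' @param y numeric outcome vector.
#' @param centiles lower centiles X (in (0, 50)) at which to report the
#'   intercentile range; the default covers the two used in practice.
#' @return An object of class `"outcome_summary"`: list with `variance`,
#'   `range`, `icr` (named by centile), and `n`.
#' @details The statistics are computed by the same compiled routines the
#'   tree grower applies to each node, so a node holding exactly the summary
#'   sample reproduces these values bit-for-bit (which is what makes the
#'   `theta = 1` limiting behaviour of the dispersion rules exact).
#' @examples
#' outcome_summary(0:10)$icr  # 25-75% intercentile range of 0..10 is 5
#' @export
outcome_summary <- function(y, centiles = c(10, 25)) {
  if (length(y) < 1L) stopf("outcome vector must be non-empty")
  y <- as.numeric(y)
  if (!all(is.finite(y))) stopf("outcome vector must be finite")
  if (any(centiles <= 0 | centiles >= 50)) stopf("centiles must lie in (0, 50)")
  base <- cpp_dispersion(y, centiles[1])
  icr <- vapply(centiles, function(X) cpp_dispersion(y, X)$icr, numeric(1))
  names(icr) <- as.character(centiles)
  structure(list(variance = base$variance,
                 range = base$range,
                 icr = icr,
                 n = length(y)),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Outcome summary (n = %d): variance %.6g, range %.6g\n",
              x$n, x$variance, x$range))
  for (nm in names(x$icr)) {
    cat(sprintf("  %s-%s%% intercentile range: %.6g\n", nm,
                100 - as.numeric(nm), x$icr[[nm]]))
  }
  invisible(x)
}

#' Validate a train/test dataset pair
#'
#' Checks that two datasets share the same feature schema and outcome name,
#' returning the pair unchanged.  Use before a hold-out evaluation in which
#' one sample trains the forest and the other measures its error.
#'
#' @param train,test `"reg_dataset"` objects.
#' @return Invisibly, `list(train = train, test = test)`.
#' @export
check_schema <- function(train, test) {
  stopifnot(inherits(train, "reg_dataset"), inherits(test, "reg_dataset"))
  if (!identical(train$feature_names, test$feature_names)) {
    stopf("train and test feature columns differ")
  }
  if (!identical(train$outcome_name, test$outcome_name)) {
    stopf("train and test outcome names differ")
  }
  invisible(list(train = train, test = test))
}

#' Seeded k-fold partition of observation indices
#'
#' Partitions `1:n` into `k` disjoint folds of near-equal size (differing by
#' at most one) by a seeded uniform shuffle.  The same seed always yields the
#' same partition; the caller's RNG state is untouched.
#'
#' @param n number of observations.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @return List of `k` integer vectors.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k < 2 || k > n) stopf("need 2 <= k <= n (got k = %s, n = %s)", k, n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(perm, rep(seq_len(k), times = sizes))
}
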