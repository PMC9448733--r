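#' Weighted mean square prediction error
#'
#' \deqn{MSPE = \sum_i w_i (y_i - \hat y_i)^2 / \sum_i w_i}
#' with unit weights by default.  Invariant to uniform rescaling of the
#' weights.
#'
#' @param y_true,y_pred observed and predicted outcome vectors.
#' @param weights optional strictly positive weights (e.g. survey weights).
#' @return A single non-negative number.
#' @export
mspe <- function(y_true, y_pred, weights = NULL) {
  if (length(y_true) != length(y_pred)) stopf("y_true and y_pred lengths differ")
  if (length(y_true) < 1L) stopf("need at least one observation")
  w <- weights %||% rep(1, length(y_true))
  if (length(w) != length(y_true)) stopf("weights length differs from y")
  if (any(w <= 0)) stopf("weights must be strictly positive")
  sum(w * (y_true - y_pred)^2) / sum(w)
}

#' Hold-out MSPE of a stopping-rule forest
#'
#' Fits a forest on the training sample and reports the weighted MSPE on a
#' held-out test sample, weighting squared errors by the *test* weights.
#'
#' @param train,test `"reg_dataset"` objects sharing the same schema (see
#'   [check_schema()]).
#' @param ntree,mtry,maxnodes,stopping,seed forest parameters, passed to
#'   [stoprf()].
#' @return An object of class `"stoprf_eval"`: list with `mspe`, `n_test`,
#'   and the parameters used.
#' @export
holdout_mspe <- function(train, test, ntree = 1000L, mtry = NULL,
                         maxnodes = 1000L,
                         stopping = stopping_control(min_parent = 5),
                         seed = 1L) {
  check_schema(train, test)
  fit <- stoprf(train$x, train$y, ntree = ntree, mtry = mtry,
                maxnodes = maxnodes, stopping = stopping, seed = seed,
                keep.data = FALSE)
  pred <- predict(fit, test$x)
  structure(list(mspe = mspe(test$y, pred, test$w),
                 method = "holdout", n_test = test$n,
                 ntree = fit$ntree, mtry = fit$mtry, maxnodes = fit$maxnodes,
                 stopping = stopping, seed = seed),
            class = "stoprf_eval")
}

#' Cross-validated MSPE of a stopping-rule forest
#'
#' Tenfold (by default) cross-validation: observations are partitioned by a
#' seeded shuffle ([kfold_indices()]); for each fold a forest is fitted on
#' the complement and evaluated on the fold.  The reported error pools the
#' weighted squared errors over all folds before dividing by the total
#' weight, so unequal fold sizes are handled exactly (this is *not* the mean
#' of per-fold MSEs).
#'
#' @param dataset a `"reg_dataset"`, or anything accepted by `x`/`y` below.
#' @param x,y,w alternative direct interface: feature matrix, outcome,
#'   optional weights.
#' @param k number of folds.
#' @param ntree,mtry,maxnodes,stopping forest parameters.
#' @param seed base seed; each fold's forest gets a sub-seed derived from it.
#' @param cv_seed seed for the fold partition (defaults to `seed`, so a
#'   sweep can share folds while varying forest seeds).
#' @return An object of class `"stoprf_eval"` with `mspe`, and `per_fold`, a
#'   data frame of fold sizes, pooled SSEs and weights that recombine to
#'   `mspe` exactly.
#' @export
cv_mspe <- function(dataset = NULL, x = NULL, y = NULL, w = NULL, k = 10L,
                    ntree = 1000L, mtry = NULL, maxnodes = 1000L,
                    stopping = stopping_control(min_parent = 5),
                    seed = 1L, cv_seed = seed) {
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "reg_dataset"))
    x <- dataset$x; y <- dataset$y; w <- dataset$w
  }
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  w <- w %||% rep(1, length(y))
  n <- length(y)
  folds <- kfold_indices(n, k, seed = cv_seed)
  sse <- wsum <- numeric(length(folds))
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    fit <- stoprf(x[-hold, , drop = FALSE], y[-hold], ntree = ntree,
                  mtry = mtry, maxnodes = maxnodes, stopping = stopping,
                  seed = derive_seed(seed, i), keep.data = FALSE)
    pred <- predict(fit, x[hold, , drop = FALSE])
    sse[i] <- sum(w[hold] * (y[hold] - pred)^2)
    wsum[i] <- sum(w[hold])
  }
  structure(list(mspe = sum(sse) / sum(wsum),
                 method = "cv", k = length(folds),
                 per_fold = data.frame(fold = seq_along(folds),
                                       n = lengths(folds),
                                       sse = sse, weight = wsum,
                                       mspe = sse / wsum),
                 ntree = ntree, mtry = mtry, maxnodes = maxnodes,
                 stopping = stopping, seed = seed, cv_seed = cv_seed),
            class = "stoprf_eval")
}

#' @export
print.stoprf_eval <- function(x, ...) {
  lab <- if (identical(x$method, "cv")) sprintf("%d-fold CV", x$k) else "hold-out"
  cat(sprintf("%s MSPE: %.6g\n", lab, x$mspe))
  invisible(x)
}

default_grid <- function(rule) {
  switch(rule,
         parent = c(2, 5, 10, 25, 50, 100),
         leaf = c(1, 2, 5, 10, 25, 50),
         variance = ,
         range = ,
         icr = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5),
         stopf("unknown rule '%s'", rule))
}

single_rule_control <- function(rule, value, icr_centile) {
  switch(rule,
         parent = stopping_control(min_parent = value),
         leaf = stopping_control(min_leaf = value),
         variance = stopping_control(theta_variance = value),
         range = stopping_control(theta_range = value),
         icr = stopping_control(theta_icr = value, icr_centile = icr_centile))
}

#' Threshold sweep for one stopping rule
#'
#' Evaluates the cross-validated (or hold-out) MSPE over a grid of threshold
#' values for a single stopping rule, with all other rules disabled, and
#' reports the minimum MSPE (minMSPE) and the threshold attaining it (ties
#' broken toward the smaller threshold).  Each (grid point, fold) forest gets
#' its own deterministically derived seed; the fold partition is shared
#' across the grid so curves are comparable.
#'
#' @param dataset a `"reg_dataset"` (or use `x`/`y`/`w`).
#' @param rule one of `"parent"`, `"leaf"`, `"variance"`, `"range"`, `"icr"`.
#' @param grid threshold grid: node sizes for `"parent"`/`"leaf"`,
#'   proportions in `[0, 1]` for the dispersion rules.  Defaults bracket
#'   common package defaults (regression leaf default 5).
#' @param icr_centile lower centile X for the `"icr"` rule.
#' @param x,y,w direct data interface.
#' @param test optional held-out `"reg_dataset"`; when supplied, hold-out
#'   MSPE replaces cross-validation.
#' @param k,ntree,mtry,maxnodes,seed evaluation and forest parameters.
#' @return An object of class `"stoprf_sweep"`: `curve` (data frame of
#'   threshold and mspe), `min_mspe`, `best_threshold`, plus the settings.
#' @examples
#' \donttest{
#' d <- gen_piecewise(120, noise_sd = 1, seed = 1)
#' sw <- tune_stoprf(d, rule = "variance", ntree = 25, k = 5, seed = 1)
#' sw
#' }
#' @export
tune_stoprf <- function(dataset = NULL, rule = c("parent", "leaf", "variance",
                                                 "range", "icr"),
                        grid = NULL, icr_centile = 25, x = NULL, y = NULL,
                        w = NULL, test = NULL, k = 10L, ntree = 1000L,
                        mtry = NULL, maxnodes = 1000L, seed = 1L) {
  rule <- match.arg(rule)
  grid <- grid %||% default_grid(rule)
  if (length(grid) < 1L) stopf("threshold grid must be non-empty")
  grid <- sort(grid)
  if (!is.null(dataset)) {
    stopifnot(inherits(dataset, "reg_dataset"))
    x <- dataset$x; y <- dataset$y; w <- dataset$w
  }
  mspes <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ctl <- single_rule_control(rule, grid[i], icr_centile)
    mspes[i] <- if (!is.null(test)) {
      train_i <- if (!is.null(dataset)) dataset else new_reg_dataset(
        as_feature_matrix(x), y, w %||% rep(1, length(y)), "y")
      holdout_mspe(train_i, test, ntree = ntree, mtry = mtry,
                   maxnodes = maxnodes, stopping = ctl,
                   seed = derive_seed(seed, i))$mspe
    } else {
      cv_mspe(x = x, y = y, w = w, k = k, ntree = ntree, mtry = mtry,
              maxnodes = maxnodes, stopping = ctl,
              seed = derive_seed(seed, i, 1L), cv_seed = seed)$mspe
    }
  }
  best <- which.min(mspes)  # first minimum = smallest threshold on ties
  structure(list(curve = data.frame(threshold = grid, mspe = mspes),
                 rule = rule, icr_centile = icr_centile,
                 min_mspe = mspes[best], best_threshold = grid[best],
                 k = k, ntree = ntree, mtry = mtry, maxnodes = maxnodes,
                 seed = seed, method = if (is.null(test)) "cv" else "holdout"),
            class = "stoprf_sweep")
}

#' @export
print.stoprf_sweep <- function(x, ...) {
  cat(sprintf("Stopping-rule sweep: %s rule (%s)\n", x$rule,
              if (x$method == "cv") sprintf("%d-fold CV", x$k) else "hold-out"))
  print(x$curve, row.names = FALSE)
  cat(sprintf("minMSPE %.6g at threshold %g\n", x$min_mspe, x$best_threshold))
  invisible(x)
}

#' @export
plot.stoprf_sweep <- function(x, ...) {
  logx <- if (x$rule %in% c("variance", "range", "icr") &&
              all(x$curve$threshold > 0)) "x" else ""
  plot(x$curve$threshold, x$curve$mspe, type = "b", log = logx,
       xlab = sprintf("%s threshold", x$rule), ylab = "MSPE",
       main = "Stopping-rule threshold sweep", ...)
  abline(h = x$min_mspe, lty = 3)
  points(x$best_threshold, x$min_mspe, pch = 19)
  invisible(x)
}

#' Percentage excess MSPE over the best rule per dataset
#'
#' For a rule-by-dataset matrix of (positive) MSPE values, computes for each
#' dataset column the percentage increase of every rule over the column's
#' best (smallest) value: `100 * (value / min - 1)`.  The best rule per
#' dataset therefore maps to 0.
#'
#' @param mspe_table numeric matrix, rules in rows, datasets in columns.
#' @return Matrix of the same shape, in percent.
#' @export
relative_excess <- function(mspe_table) {
  m <- as.matrix(mspe_table)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0)) {
    stopf("mspe_table must be strictly positive and finite")
  }
  sweep(m, 2, apply(m, 2, min), function(v, mn) 100 * (v / mn - 1))
}
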