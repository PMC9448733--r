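#' Fit a stopping-rule regression random forest
#'
#' Grows `ntree` CART regression trees, each on a uniform bootstrap resample
#' of the training data (size n, with replacement), with `mtry` candidate
#' features drawn per node, and averages their predictions.  Tree expansion is
#' governed by the stopping configuration: minimum parent size, minimum leaf
#' size, and/or node-dispersion thresholds (variance, range, intercentile
#' range) expressed relative to the full, un-bootstrapped training outcome —
#' see [stopping_control()].
#'
#' All randomness flows from `seed` through an internal generator, so a fit
#' is bit-reproducible and independent of the session RNG state.  Bootstrap
#' sampling is unweighted; survey weights enter only at evaluation time
#' ([mspe()] and friends).
#'
#' @param x feature matrix or data frame (coerced column-wise to numeric),
#'   or a model formula.
#' @param y numeric outcome vector (default method).
#' @param ntree number of trees (bootstrap replicates).
#' @param mtry candidate features per node; default `max(1, floor(p/3))`.
#' @param maxnodes cap on terminal nodes per tree.
#' @param stopping a [stopping_control()]; the default reproduces the
#'   classical parent-node-size rule with Breiman's regression default of 5.
#' @param seed integer seed.
#' @param keep.inbag record the bootstrap multiplicity of every observation
#'   in every tree (an `n x ntree` count matrix).
#' @param keep.data store the training data in the fit (needed by
#'   [fitted()]/[residuals()]).
#' @param ... unused.
#' @return An object of class `"stoprf"`.
#' @examples
#' d <- gen_piecewise(150, seed = 7)
#' fit <- stoprf(d$x, d$y, ntree = 50, stopping = stopping_control(min_leaf = 5))
#' fit
#' mspe(d$y, fitted(fit))
#' @export
stoprf <- function(x, ...) UseMethod("stoprf")

#' @rdname stoprf
#' @param formula,data model formula and data frame for the formula method.
#' @export
stoprf.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  fit <- stoprf.default(x, y, ...)
  fit$call <- match.call()
  fit$outcome_name <- deparse(formula[[2]])
  fit
}

#' @rdname stoprf
#' @export
stoprf.default <- function(x, y, ntree = 1000L, mtry = NULL,
                           maxnodes = 1000L,
                           stopping = stopping_control(min_parent = 5),
                           seed = 1L, keep.inbag = FALSE, keep.data = TRUE,
                           ...) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (nrow(x) < 1L) stopf("need at least one observation")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("x and y must be finite")
  stopifnot(inherits(stopping, "stoprf_control"))
  p <- ncol(x)
  mtry <- mtry %||% max(1L, p %/% 3L)
  if (mtry < 1 || mtry > p) stopf("mtry must be in 1..%d (got %s)", p, mtry)
  if (ntree < 1) stopf("ntree must be >= 1")
  if (maxnodes < 1) stopf("maxnodes must be >= 1")
  summary <- outcome_summary(y, centiles = stopping$icr_centile)
  res <- cpp_grow_forest(x, y, cfg_vector(stopping, summary),
                         as.integer(mtry), as.integer(maxnodes),
                         as.integer(ntree), as.numeric(seed),
                         isTRUE(keep.inbag))
  structure(list(trees = res$trees, inbag = res$inbag,
                 ntree = as.integer(ntree), mtry = as.integer(mtry),
                 maxnodes = as.integer(maxnodes), stopping = stopping,
                 seed = seed, summary = summary,
                 feature_names = colnames(x), n = nrow(x), p = p,
                 outcome_name = "y",
                 x = if (isTRUE(keep.data)) x else NULL,
                 y = if (isTRUE(keep.data)) y else NULL,
                 call = match.call()),
            class = "stoprf")
}

# Coerce prediction input to the feature layout the forest was trained on.
forest_newdata <- function(object, newdata) {
  if (is.data.frame(newdata) && !is.null(object$feature_names) &&
      all(object$feature_names %in% names(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$p) {
    stopf("newdata has %d columns; forest was trained on %d", ncol(x), object$p)
  }
  x
}

#' Predict from a stopping-rule forest
#'
#' @param object a fitted [stoprf()] forest.
#' @param newdata feature matrix or data frame; a data frame is matched to
#'   the training feature names when possible.
#' @param predict.all also return the individual tree predictions.
#' @param ... unused.
#' @return The vector of per-row forest predictions (unweighted mean over
#'   trees); with `predict.all = TRUE`, a list with `aggregate` and the
#'   `n x ntree` matrix `individual`.
#' @export
predict.stoprf <- function(object, newdata, predict.all = FALSE, ...) {
  x <- forest_newdata(object, newdata)
  if (nrow(x) == 0L) {
    if (isTRUE(predict.all)) {
      return(list(aggregate = numeric(0),
                  individual = matrix(numeric(0), 0, object$ntree)))
    }
    return(numeric(0))
  }
  if (isTRUE(predict.all)) {
    ind <- cpp_predict_forest(object$trees, x, TRUE)
    list(aggregate = rowMeans(ind), individual = ind)
  } else {
    as.numeric(cpp_predict_forest(object$trees, x, FALSE))
  }
}

#' @export
fitted.stoprf <- function(object, ...) {
  if (is.null(object$x)) stopf("forest was fitted with keep.data = FALSE")
  predict(object, object$x)
}

#' @export
residuals.stoprf <- function(object, ...) {
  if (is.null(object$y)) stopf("forest was fitted with keep.data = FALSE")
  object$y - fitted(object)
}

#' @export
print.stoprf <- function(x, ...) {
  cat("Stopping-rule regression random forest\n")
  cat(sprintf("  %d trees, mtry = %d, maxnodes = %d, n = %d, p = %d\n",
              x$ntree, x$mtry, x$maxnodes, x$n, x$p))
  cat(paste0("  ", format(x$stopping), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.stoprf <- function(object, ...) {
  sizes <- vapply(object$trees, function(tr) sum(tr$feature == 0L), numeric(1))
  out <- list(forest = object,
              terminal_nodes = summary(sizes),
              train_mspe = if (!is.null(object$x)) {
                mspe(object$y, predict(object, object$x))
              } else NA_real_)
  class(out) <- "summary.stoprf"
  out
}

#' @export
print.summary.stoprf <- function(x, ...) {
  print(x$forest)
  cat("  terminal nodes per tree:\n")
  print(x$terminal_nodes)
  if (is.finite(x$train_mspe)) {
    cat(sprintf("  training (resubstitution) MSPE: %.6g\n", x$train_mspe))
  }
  invisible(x)
}

#' Save / restore a fitted forest
#'
#' `write_stoprf()` serialises a fitted forest to a file; `read_stoprf()`
#' restores it.  The round trip preserves predictions bit-exactly.  Files
#' carry a format tag and version so that corrupt or foreign files are
#' rejected with a clear error.
#'
#' @param object a fitted `"stoprf"` forest.
#' @param path file path.
#' @return `write_stoprf()`: `path` invisibly; `read_stoprf()`: the forest.
#' @export
write_stoprf <- function(object, path) {
  stopifnot(inherits(object, "stoprf"))
  saveRDS(list(format = "stoprf-forest", version = 1L, object = object), path)
  invisible(path)
}

#' @rdname write_stoprf
#' @export
read_stoprf <- function(path) {
  payload <- tryCatch(readRDS(path),
                      error = function(e) stopf("cannot read '%s': %s", path,
                                                conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "stoprf-forest")) {
    stopf("'%s' is not a stoprf forest file", path)
  }
  if (!identical(payload$version, 1L)) {
    stopf("unsupported stoprf forest file version: %s", payload$version)
  }
  payload$object
}
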