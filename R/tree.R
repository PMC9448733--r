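#' Best CART split of a node sample
#'
#' Exhaustive split search over the given candidate features: thresholds are
#' the midpoints of adjacent distinct sorted values, the criterion is the
#' reduction in within-node sum of squared errors, and ties are broken toward
#' the lowest feature index, then the smallest threshold.  Splits leaving a
#' child below the leaf-size limit are invalid.
#'
#' @param x numeric feature matrix of the node sample (n >= 2 rows).
#' @param y outcome values of the node sample.
#' @param features integer indices of candidate features (default: all).
#' @param min_leaf minimum child size a valid split must respect.
#' @return A list with `feature`, `threshold`, `sse_reduction`, `left_n`,
#'   `right_n`; or `NULL` when no valid split exists (all candidate features
#'   constant, or the node too small for the leaf limit).
#' @examples
#' best_split(matrix(1:4), c(0, 0, 10, 10))
#' @export
best_split <- function(x, y, features = seq_len(ncol(x)), min_leaf = 1L) {
  x <- as_feature_matrix(x)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (nrow(x) < 2L) stopf("need at least 2 observations to split")
  if (length(features) < 1L || any(features < 1 | features > ncol(x))) {
    stopf("invalid candidate feature indices")
  }
  res <- cpp_best_split(x, as.numeric(y), as.integer(features),
                        as.integer(min_leaf))
  if (length(res) == 0L) NULL else res
}

#' Grow a single regression tree under a stopping configuration
#'
#' Breadth-first CART expansion on the supplied sample.  At each node the
#' halt rules are checked first ([node_halt()] semantics), then the terminal-
#' node cap `maxnodes`; surviving nodes draw `mtry` candidate features without
#' replacement and take the best valid split ([best_split()]), becoming
#' terminal if none exists.  Leaves predict their in-node outcome mean.
#'
#' Dispersion rules compare each node against `summary`, which should be the
#' [outcome_summary()] of the *full training* outcome; by default it is
#' computed from `y` itself, appropriate when the tree is grown directly on
#' the training sample rather than on a bootstrap replicate.
#'
#' @param x,y training sample (matrix / vector).
#' @param control a [stopping_control()].
#' @param mtry number of candidate features per node (default: all).
#' @param maxnodes cap on the number of terminal nodes.
#' @param seed integer seed for the feature subsampling stream.
#' @param summary full-training [outcome_summary()] anchoring the dispersion
#'   rules.
#' @return An object of class `"stoprf_tree"`.
#' @export
grow_tree <- function(x, y, control = stopping_control(min_parent = 5),
                      mtry = NULL, maxnodes = .Machine$integer.max %/% 2,
                      seed = 1L, summary = NULL) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  if (nrow(x) < 1L) stopf("need at least one observation")
  stopifnot(inherits(control, "stoprf_control"))
  p <- ncol(x)
  mtry <- mtry %||% p
  if (mtry < 1 || mtry > p) stopf("mtry must be in 1..%d", p)
  if (maxnodes < 1) stopf("maxnodes must be >= 1")
  summary <- summary %||% outcome_summary(y, centiles = control$icr_centile)
  nodes <- cpp_grow_tree(x, y, cfg_vector(control, summary),
                         as.integer(mtry), as.integer(maxnodes),
                         as.numeric(seed))
  structure(c(nodes, list(control = control, mtry = mtry,
                          feature_names = colnames(x), nobs = nrow(x))),
            class = "stoprf_tree")
}

#' @export
predict.stoprf_tree <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) < max(1L, max(object$feature))) {
    stopf("newdata has too few columns for this tree")
  }
  if (nrow(x) == 0L) return(numeric(0))
  cpp_predict_tree(unclass(object)[c("feature", "threshold", "left", "right",
                                     "n", "value")], x)
}

#' @export
print.stoprf_tree <- function(x, ...) {
  s <- tree_size_stats(x)
  cat(sprintf("Regression tree: %d terminal nodes, depth %d, n = %d\n",
              s$terminal_count, s$depth, x$nobs))
  invisible(x)
}

#' Size statistics of a fitted tree
#'
#' @param tree a `"stoprf_tree"`, or one raw tree from a fitted forest.
#' @return List with `terminal_count`, `depth` (0 for a root-only tree), and
#'   `min_leaf_n`, the smallest leaf sample size.
#' @export
tree_size_stats <- function(tree) {
  is_leaf <- tree$feature == 0L
  depth <- integer(length(tree$feature))
  for (i in seq_along(depth)) {  # parents precede children in creation order
    if (!is_leaf[i]) {
      depth[tree$left[i]] <- depth[i] + 1L
      depth[tree$right[i]] <- depth[i] + 1L
    }
  }
  list(terminal_count = sum(is_leaf),
       depth = max(depth),
       min_leaf_n = min(tree$n[is_leaf]))
}
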