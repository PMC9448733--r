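#' Tree-expansion stopping configuration
#'
#' Bundles the five alternative stopping criteria that can halt tree growth.
#' A node is *halted* (made terminal before any split is attempted) when any
#' enabled halt rule triggers:
#'
#' * **variance** — the population variance of the outcome in the node is at
#'   most `theta_variance` times the variance in the full training set;
#' * **range** — node range (max - min) at most `theta_range` times the full
#'   training range;
#' * **intercentile range** — node \eqn{[X, 100-X]} intercentile range at most
#'   `theta_icr` times the full-training value, for `icr_centile = X`;
#' * **parent size** — the node holds fewer than `min_parent` observations.
#'
#' The fifth criterion, `min_leaf`, is a constraint on candidate splits rather
#' than a halt: a split is invalid if either child would hold fewer than
#' `min_leaf` observations, and a node with no valid split becomes terminal.
#' Parent- and leaf-size limits are not equivalent: requiring leaves of size
#' at least n forces every split parent to have at least 2n observations, but
#' a parent-size limit of 2n still admits splits as lopsided as 1/(2n-1).
#'
#' All comparisons are non-strict, so `theta = 1` makes the root itself halt
#' whenever its statistic does not exceed the training total, and `theta = 0`
#' halts exactly the constant-outcome nodes.
#'
#' @param theta_variance,theta_range,theta_icr dispersion thresholds in
#'   `[0, 1]`, or `NULL` to disable the rule.
#' @param icr_centile lower centile X of the intercentile range `[X, 100-X]`,
#'   in (0, 50).  Typical choices are 10 and 25.
#' @param min_parent minimum node size required to attempt a split
#'   (integer >= 2), or `NULL` to disable.
#' @param min_leaf minimum child size a split must respect (integer >= 1), or
#'   `NULL` to disable.
#' @return An object of class `"stoprf_control"`.
#' @examples
#' stopping_control(min_parent = 5)              # Breiman's classical rule
#' stopping_control(theta_icr = 0.05, icr_centile = 25)
#' @export
stopping_control <- function(theta_variance = NULL, theta_range = NULL,
                             theta_icr = NULL, icr_centile = 25,
                             min_parent = NULL, min_leaf = NULL) {
  chk_theta <- function(v, nm) {
    if (is.null(v)) return(NULL)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stopf("%s must be a single value in [0, 1]", nm)
    }
    as.numeric(v)
  }
  theta_variance <- chk_theta(theta_variance, "theta_variance")
  theta_range <- chk_theta(theta_range, "theta_range")
  theta_icr <- chk_theta(theta_icr, "theta_icr")
  if (!is.numeric(icr_centile) || length(icr_centile) != 1L ||
      icr_centile <= 0 || icr_centile >= 50) {
    stopf("icr_centile must lie in (0, 50)")
  }
  if (!is.null(min_parent)) {
    if (min_parent < 2 || min_parent != round(min_parent)) {
      stopf("min_parent must be an integer >= 2")
    }
    min_parent <- as.integer(min_parent)
  }
  if (!is.null(min_leaf)) {
    if (min_leaf < 1 || min_leaf != round(min_leaf)) {
      stopf("min_leaf must be an integer >= 1")
    }
    min_leaf <- as.integer(min_leaf)
  }
  enabled <- !vapply(list(theta_variance, theta_range, theta_icr,
                          min_parent, min_leaf), is.null, logical(1))
  if (!any(enabled)) stopf("at least one stopping criterion must be enabled")
  structure(list(theta_variance = theta_variance, theta_range = theta_range,
                 theta_icr = theta_icr, icr_centile = as.numeric(icr_centile),
                 min_parent = min_parent, min_leaf = min_leaf),
            class = "stoprf_control")
}

#' @export
format.stoprf_control <- function(x, ...) {
  out <- character(0)
  if (!is.null(x$min_parent)) {
    out <- c(out, sprintf("parent node size >= %d required to split", x$min_parent))
  }
  if (!is.null(x$min_leaf)) {
    out <- c(out, sprintf("every leaf must hold >= %d observations", x$min_leaf))
  }
  if (!is.null(x$theta_variance)) {
    out <- c(out, sprintf("halt when node variance <= %g x total variance",
                          x$theta_variance))
  }
  if (!is.null(x$theta_range)) {
    out <- c(out, sprintf("halt when node range <= %g x total range", x$theta_range))
  }
  if (!is.null(x$theta_icr)) {
    out <- c(out, sprintf("halt when node %g-%g%% intercentile range <= %g x total",
                          x$icr_centile, 100 - x$icr_centile, x$theta_icr))
  }
  out
}

#' @export
print.stoprf_control <- function(x, ...) {
  cat("Stopping rules:\n")
  cat(paste0("  - ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

# Pack control + full-training summary into the numeric vector the C++ core
# consumes.  -1 marks a disabled dispersion rule, 0 a disabled size rule.
cfg_vector <- function(control, summary) {
  icr_tot <- 0
  if (!is.null(control$theta_icr)) {
    key <- as.character(control$icr_centile)
    if (!key %in% names(summary$icr)) {
      stopf("summary lacks the %s%% intercentile range required by the control",
            key)
    }
    icr_tot <- summary$icr[[key]]
  }
  c(control$theta_variance %||% -1,
    control$theta_range %||% -1,
    control$theta_icr %||% -1,
    control$icr_centile,
    control$min_parent %||% 0,
    control$min_leaf %||% 0,
    summary$variance,
    summary$range,
    icr_tot)
}

#' Halt decision for a single node
#'
#' Applies the enabled halt rules (dispersion thresholds and parent-size
#' limit) to the outcome values held by a candidate node, relative to the
#' full-training summary.  The leaf-size criterion does not participate: it
#' constrains candidate splits instead (see [split_respects_leaf_size()]).
#'
#' @param y_node outcome values in the node (the in-bag sample it holds).
#' @param summary an [outcome_summary()] of the full training outcome.
#' @param control a [stopping_control()].
#' @return List with `halt` (logical) and `triggered`, a character subset of
#'   `c("variance", "range", "icr", "parent_size")`; `halt` is `TRUE` exactly
#'   when `triggered` is non-empty.
#' @export
node_halt <- function(y_node, summary, control) {
  stopifnot(inherits(summary, "outcome_summary"), inherits(control, "stoprf_control"))
  if (length(y_node) < 1L) stopf("node outcome vector must be non-empty")
  triggered <- character(0)
  n <- length(y_node)
  if (!is.null(control$min_parent) && n < control$min_parent) {
    triggered <- c(triggered, "parent_size")
  }
  stats <- cpp_dispersion(as.numeric(y_node), control$icr_centile)
  if (!is.null(control$theta_variance) &&
      stats$variance <= control$theta_variance * summary$variance) {
    triggered <- c(triggered, "variance")
  }
  if (!is.null(control$theta_range) &&
      stats$range <= control$theta_range * summary$range) {
    triggered <- c(triggered, "range")
  }
  if (!is.null(control$theta_icr)) {
    key <- as.character(control$icr_centile)
    if (!key %in% names(summary$icr)) {
      stopf("summary lacks the %s%% intercentile range required by the control", key)
    }
    if (stats$icr <= control$theta_icr * summary$icr[[key]]) {
      triggered <- c(triggered, "icr")
    }
  }
  list(halt = length(triggered) > 0L, triggered = triggered)
}

#' Does a candidate split respect the leaf-size criterion?
#'
#' @param left_n,right_n child sizes of the candidate split.
#' @param control a [stopping_control()].
#' @return `TRUE` iff both children reach `min_leaf` (always `TRUE` when the
#'   rule is disabled).
#' @export
split_respects_leaf_size <- function(left_n, right_n, control) {
  stopifnot(inherits(control, "stoprf_control"), left_n >= 1, right_n >= 1)
  if (is.null(control$min_leaf)) return(TRUE)
  min(left_n, right_n) >= control$min_leaf
}
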