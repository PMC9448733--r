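# Independent exhaustive-search CART implementation, used as the reference
# the compiled tree grower is compared against on tiny datasets.  Same split
# criterion and tie-break contract (ascending feature then threshold, ties
# resolved by a relative tolerance), written from scratch in plain R.

oracle_best_split <- function(x, y, min_leaf = 1L) {
  n <- nrow(x)
  if (n < 2 || 2 * min_leaf > n) return(NULL)
  best <- NULL
  best_crit <- -Inf
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    ys <- y[ord]
    cum <- cumsum(ys)
    tot <- cum[n]
    for (i in seq_len(n - 1)) {
      if (xs[i + 1] == xs[i]) next
      nl <- i
      nr <- n - i
      if (nl < min_leaf || nr < min_leaf) next
      sl <- cum[i]
      sr <- tot - sl
      crit <- sl^2 / nl + sr^2 / nr
      tol <- if (is.finite(best_crit)) 1e-9 * max(1, abs(best_crit)) else 0
      if (is.null(best) || crit > best_crit + tol) {
        best_crit <- crit
        best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                     left_n = nl, right_n = nr)
      }
    }
  }
  best
}

oracle_grow <- function(x, y, min_leaf = 1L) {
  node <- list(n = length(y), value = mean(y))
  sp <- oracle_best_split(x, y, min_leaf)
  if (is.null(sp)) return(node)
  go_left <- x[, sp$feature] <= sp$threshold
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- oracle_grow(x[go_left, , drop = FALSE], y[go_left], min_leaf)
  node$right <- oracle_grow(x[!go_left, , drop = FALSE], y[!go_left], min_leaf)
  node
}

# Structural comparison of a flat stoprf tree against an oracle tree,
# walking both from the root.  Returns a character vector of mismatches.
compare_tree_to_oracle <- function(tree, oracle, id = 1L, path = "root") {
  probs <- character(0)
  leaf <- tree$feature[id] == 0L
  oleaf <- is.null(oracle$feature)
  if (leaf != oleaf) {
    return(sprintf("%s: leaf status differs (tree %s, oracle %s)",
                   path, leaf, oleaf))
  }
  if (tree$n[id] != oracle$n) {
    probs <- c(probs, sprintf("%s: n %d vs %d", path, tree$n[id], oracle$n))
  }
  if (abs(tree$value[id] - oracle$value) > 1e-9 * max(1, abs(oracle$value))) {
    probs <- c(probs, sprintf("%s: mean differs", path))
  }
  if (!leaf) {
    if (tree$feature[id] != oracle$feature ||
        abs(tree$threshold[id] - oracle$threshold) > 1e-12) {
      probs <- c(probs, sprintf("%s: split (%d, %g) vs (%d, %g)", path,
                                tree$feature[id], tree$threshold[id],
                                oracle$feature, oracle$threshold))
    } else {
      probs <- c(probs,
                 compare_tree_to_oracle(tree, oracle$left, tree$left[id],
                                        paste0(path, "L")),
                 compare_tree_to_oracle(tree, oracle$right, tree$right[id],
                                        paste0(path, "R")))
    }
  }
  probs
}

# Direct (loop-based) weighted MSPE for cross-checking pooled computations.
direct_weighted_mspe <- function(y, yhat, w) {
  num <- 0
  den <- 0
  for (i in seq_along(y)) {
    num <- num + w[i] * (y[i] - yhat[i])^2
    den <- den + w[i]
  }
  num / den
}

pop_var <- function(y) mean((y - mean(y))^2)
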