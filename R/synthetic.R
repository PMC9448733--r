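#' Piecewise-constant synthetic regression data
#'
#' One feature uniform on \[0, 1\]; the outcome is a step function of the
#' feature plus Gaussian noise.  With `noise_sd = 0` a tree carrying the true
#' cut structure achieves zero error, which makes this the basic fixture for
#' verifying split recovery and the stopping rules.
#'
#' @param n sample size.
#' @param cuts strictly increasing cut points inside (0, 1).
#' @param leaf_means segment means, one more than there are cuts.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A `"reg_dataset"` with a single feature `x`.
#' @export
gen_piecewise <- function(n, cuts = c(0.3, 0.6), leaf_means = c(0, 4, 10),
                          noise_sd = 1, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  if (is.unsorted(cuts, strictly = TRUE)) stopf("cuts must be strictly increasing")
  if (length(leaf_means) != length(cuts) + 1L) {
    stopf("need length(cuts) + 1 leaf means")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  dat <- with_seed(seed, {
    x <- stats::runif(n)
    y <- leaf_means[findInterval(x, cuts) + 1L] + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = y)
  })
  xm <- matrix(dat$x, ncol = 1, dimnames = list(NULL, "x"))
  new_reg_dataset(xm, dat$y, rep(1, n), "y")
}

#' Friedman #1 synthetic regression benchmark
#'
#' Ten independent uniform features on \[0, 1\]; the outcome is
#' \deqn{y = 10 \sin(\pi x_1 x_2) + 20 (x_3 - 0.5)^2 + 10 x_4 + 5 x_5 + \epsilon,}
#' so features 6-10 are inert.  The standard nonlinear test function for
#' regression forests, with known noiseless values.
#'
#' @param n sample size.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A `"reg_dataset"` with features `x1`..`x10`.
#' @export
gen_friedman1 <- function(n, noise_sd = 1, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  dat <- with_seed(seed, {
    x <- matrix(stats::runif(n * 10L), n, 10L)
    y <- friedman1_mean(x) + stats::rnorm(n, 0, noise_sd)
    list(x = x, y = y)
  })
  colnames(dat$x) <- paste0("x", 1:10)
  new_reg_dataset(dat$x, dat$y, rep(1, n), "y")
}

#' Noiseless Friedman #1 regression function
#'
#' @param x matrix with at least 5 columns of values in \[0, 1\].
#' @return The vector of noiseless outcomes.
#' @export
friedman1_mean <- function(x) {
  x <- as_feature_matrix(x)
  10 * sin(pi * x[, 1] * x[, 2]) + 20 * (x[, 3] - 0.5)^2 +
    10 * x[, 4] + 5 * x[, 5]
}

#' Suite of tiny random datasets for exhaustive-search tree checks
#'
#' Generates small random regression datasets (mixed continuous and
#' few-valued "categorical-as-numeric" columns; every other dataset has its
#' outcome rounded to half-integers so tied outcomes and tied split gains are
#' exercised).  Sized so an exhaustive CART oracle remains fast.
#'
#' @param count number of datasets.
#' @param max_n,max_p size bounds (`max_n <= 30`, `max_p <= 4`).
#' @param seed integer seed.
#' @return List of `"reg_dataset"` objects.
#' @export
gen_oracle_suite <- function(count = 50L, max_n = 30L, max_p = 4L, seed = 1L) {
  if (max_n > 30 || max_p > 4) stopf("suite bounds are max_n <= 30, max_p <= 4")
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      n <- sample(5:max_n, 1L)
      p <- sample(seq_len(max_p), 1L)
      x <- matrix(0, n, p)
      for (j in seq_len(p)) {
        x[, j] <- if (stats::runif(1) < 0.35) {
          sample(0:3, n, replace = TRUE)      # few-valued numeric coding
        } else {
          stats::runif(n)
        }
      }
      colnames(x) <- paste0("x", seq_len(p))
      y <- stats::rnorm(n, mean = x[, 1], sd = 1)
      if (i %% 2L == 0L) y <- round(y * 2) / 2  # force tied outcomes
      new_reg_dataset(x, y, rep(1, n), "y")
    })
  })
}
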