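test_that("weighted MSPE arithmetic", {
  expect_equal(mspe(c(1, 2), c(1, 4)), 2)
  expect_equal(mspe(c(1, 2), c(1, 4), weights = c(1, 3)), 3)
  expect_equal(mspe(1:5, 1:5), 0)
  expect_error(mspe(1:3, 1:4), "lengths differ")
  expect_error(mspe(1:2, 1:2, weights = c(1, 0)), "strictly positive")
  # invariance to uniform weight rescaling; equals unweighted under equal weights
  set.seed(1)
  y <- rnorm(20); yh <- rnorm(20); w <- runif(20, 0.5, 4)
  expect_equal(mspe(y, yh, w), mspe(y, yh, 100 * w))
  expect_equal(mspe(y, yh, rep(2, 20)), mspe(y, yh))
  expect_equal(mspe(y, yh, w), direct_weighted_mspe(y, yh, w))
})

test_that("cross-validated MSPE pools weighted errors over folds", {
  d <- gen_piecewise(47, noise_sd = 0.7, seed = 50)
  d$w <- runif(47, 0.5, 3)
  res <- cv_mspe(d, k = 4, ntree = 10, stopping = stopping_control(min_leaf = 2),
                 seed = 3)
  # per-fold pieces recombine to the pooled value exactly
  expect_equal(res$mspe, sum(res$per_fold$sse) / sum(res$per_fold$weight))
  # pooled result differs from the naive mean of per-fold MSEs (unequal folds)
  expect_false(isTRUE(all.equal(res$mspe, mean(res$per_fold$mspe))))

  # independent re-implementation: same folds, same per-fold forest seeds
  folds <- kfold_indices(47, 4, seed = 3)
  num <- den <- 0
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    f <- stoprf(d$x[-hold, , drop = FALSE], d$y[-hold], ntree = 10,
                stopping = stopping_control(min_leaf = 2),
                seed = stoprf:::derive_seed(3, i), keep.data = FALSE)
    err <- d$y[hold] - predict(f, d$x[hold, , drop = FALSE])
    num <- num + sum(d$w[hold] * err^2)
    den <- den + sum(d$w[hold])
  }
  expect_equal(res$mspe, num / den)

  # constant outcome -> zero error whatever the parameters
  dc <- d
  dc$y <- rep(4, 47)
  expect_equal(cv_mspe(dc, k = 4, ntree = 5, seed = 1)$mspe, 0)
})

test_that("leave-one-out equals a direct loop on tiny data", {
  d <- gen_piecewise(10, noise_sd = 0.5, seed = 60)
  res <- cv_mspe(d, k = 10, ntree = 8, stopping = stopping_control(min_leaf = 1),
                 seed = 2)
  folds <- kfold_indices(10, 10, seed = 2)
  errs <- vapply(seq_along(folds), function(i) {
    hold <- folds[[i]]
    f <- stoprf(d$x[-hold, , drop = FALSE], d$y[-hold], ntree = 8,
                stopping = stopping_control(min_leaf = 1),
                seed = stoprf:::derive_seed(2, i), keep.data = FALSE)
    (d$y[hold] - predict(f, d$x[hold, , drop = FALSE]))^2
  }, numeric(1))
  expect_equal(res$mspe, mean(errs))
})

test_that("hold-out evaluation is deterministic and near-zero on memorised data", {
  train <- gen_piecewise(60, noise_sd = 0, seed = 70)
  r1 <- holdout_mspe(train, train, ntree = 60, maxnodes = 500,
                     stopping = stopping_control(min_leaf = 1), seed = 1)
  r2 <- holdout_mspe(train, train, ntree = 60, maxnodes = 500,
                     stopping = stopping_control(min_leaf = 1), seed = 1)
  expect_identical(r1$mspe, r2$mspe)
  expect_lt(r1$mspe, 0.05 * pop_var(train$y))
})

test_that("threshold sweep reports the grid minimum with low-threshold ties", {
  d <- gen_piecewise(60, noise_sd = 0.8, seed = 80)
  sw <- tune_stoprf(d, rule = "leaf", grid = c(5), ntree = 10, k = 3, seed = 4)
  expect_equal(sw$min_mspe, sw$curve$mspe[1])
  expect_equal(sw$best_threshold, 5)

  sw <- tune_stoprf(d, rule = "variance", grid = c(0.01, 0.1, 1), ntree = 10,
                    k = 3, seed = 4)
  expect_equal(sw$min_mspe, min(sw$curve$mspe))
  expect_true(all(sw$min_mspe <= sw$curve$mspe))
  # a grid point reproduces a direct CV call with the same derived seed
  i <- which(sw$curve$threshold == 0.1)
  direct <- cv_mspe(d, k = 3, ntree = 10,
                    stopping = stopping_control(theta_variance = 0.1),
                    seed = stoprf:::derive_seed(4, i, 1L), cv_seed = 4)
  expect_equal(sw$curve$mspe[i], direct$mspe)
  expect_error(tune_stoprf(d, rule = "leaf", grid = numeric(0)), "non-empty")
})

test_that("relative excess percentages follow from the column minima", {
  m <- benchmark_mspe()
  ex <- relative_excess(m)
  # best rule per dataset sits at exactly 0%
  expect_equal(unname(apply(ex, 2, min)), rep(0, ncol(m)))
  for (j in seq_len(ncol(m))) {
    expect_equal(ex[which.min(m[, j]), j], 0)
  }
  # spot value: parent-rule excess on the servo column
  expect_equal(unname(ex["parent", "servo"]),
               100 * (0.2729 / 0.2235 - 1), tolerance = 1e-12)
  expect_error(relative_excess(matrix(c(1, -1), 1)), "positive")
})
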