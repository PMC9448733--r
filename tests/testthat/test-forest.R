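test_that("forest fits are deterministic given the seed", {
  d <- gen_friedman1(80, seed = 10)
  f1 <- stoprf(d$x, d$y, ntree = 30, seed = 7, keep.data = FALSE)
  f2 <- stoprf(d$x, d$y, ntree = 30, seed = 7, keep.data = FALSE)
  newx <- gen_friedman1(25, seed = 11)$x
  expect_identical(predict(f1, newx), predict(f2, newx))
  f3 <- stoprf(d$x, d$y, ntree = 30, seed = 8, keep.data = FALSE)
  expect_false(identical(predict(f1, newx), predict(f3, newx)))
})

test_that("forest prediction is the mean of tree predictions, within their range", {
  d <- gen_friedman1(60, seed = 12)
  f <- stoprf(d$x, d$y, ntree = 25, stopping = stopping_control(min_leaf = 3),
              seed = 1)
  newx <- gen_friedman1(30, seed = 13)$x
  pr <- predict(f, newx, predict.all = TRUE)
  expect_equal(pr$aggregate, rowMeans(pr$individual))
  expect_equal(predict(f, newx), pr$aggregate)
  expect_true(all(pr$aggregate >= apply(pr$individual, 1, min) - 1e-12))
  expect_true(all(pr$aggregate <= apply(pr$individual, 1, max) + 1e-12))
  expect_identical(predict(f, newx[0, , drop = FALSE]), numeric(0))
  expect_error(predict(f, newx[, 1:5]), "columns")
})

test_that("single-tree forest with a full-range halt predicts the in-bag mean", {
  d <- gen_piecewise(40, noise_sd = 1, seed = 14)
  f <- stoprf(d$x, d$y, ntree = 1, stopping = stopping_control(theta_range = 1),
              seed = 5, keep.inbag = TRUE)
  ib_mean <- sum(f$inbag[, 1] * d$y) / sum(f$inbag[, 1])
  expect_equal(predict(f, matrix(runif(6), ncol = 1)), rep(ib_mean, 6))
})

test_that("mtry exceeding the feature count is rejected", {
  d <- gen_piecewise(20, seed = 1)
  expect_error(stoprf(d$x, d$y, ntree = 2, mtry = 2), "mtry")
})

test_that("increasing ntree stabilises predictions across refits", {
  d <- gen_friedman1(100, noise_sd = 1, seed = 20)
  probe <- gen_friedman1(1, seed = 21)$x
  pred_at <- function(ntree, seed) {
    f <- stoprf(d$x, d$y, ntree = ntree, mtry = 3,
                stopping = stopping_control(min_leaf = 5), seed = seed,
                keep.data = FALSE)
    predict(f, probe)
  }
  v_small <- var(vapply(1:10, function(s) pred_at(5, s), numeric(1)))
  v_large <- var(vapply(1:10, function(s) pred_at(100, s), numeric(1)))
  expect_lt(v_large, v_small)
})

test_that("serialisation round-trips predictions bit-exactly", {
  d <- gen_friedman1(50, seed = 30)
  f <- stoprf(d$x, d$y, ntree = 10, seed = 2, keep.data = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  write_stoprf(f, path)
  g <- read_stoprf(path)
  newx <- gen_friedman1(20, seed = 31)$x
  expect_identical(predict(g, newx), predict(f, newx))
  expect_identical(g$mtry, f$mtry)
  expect_identical(g$stopping, f$stopping)

  corrupt <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a forest", corrupt)
  expect_error(read_stoprf(corrupt), "cannot read")
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), other)
  expect_error(read_stoprf(other), "not a stoprf forest")
})

test_that("formula interface matches the default interface", {
  d <- gen_friedman1(60, seed = 33)
  df <- as.data.frame(d$x)
  df$y <- d$y
  f1 <- stoprf(y ~ ., data = df, ntree = 15, seed = 4)
  f2 <- stoprf(d$x, d$y, ntree = 15, seed = 4)
  expect_equal(predict(f1, df), predict(f2, d$x))
  expect_equal(residuals(f1), d$y - fitted(f1))
})

test_that("forest accuracy is comparable to an established implementation", {
  skip_if_not_installed("randomForest")
  train <- gen_friedman1(250, noise_sd = 1, seed = 40)
  test <- gen_friedman1(200, noise_sd = 1, seed = 41)
  f <- stoprf(train$x, train$y, ntree = 300, mtry = 3,
              stopping = stopping_control(min_leaf = 5), seed = 1,
              keep.data = FALSE)
  m_mine <- mspe(test$y, predict(f, test$x))
  set.seed(1)
  rf <- randomForest::randomForest(train$x, train$y, ntree = 300, mtry = 3,
                                   nodesize = 5)
  m_ref <- mspe(test$y, predict(rf, test$x))
  expect_lt(m_mine, 1.35 * m_ref)
  expect_lt(m_ref, 1.35 * m_mine)
})
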