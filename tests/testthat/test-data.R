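test_that("CSV loading validates, drops incomplete rows, and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,y,wt", "1,2,3,1", "4,,6,1", "7,8,9,2", "1,5,2,0.5"), path)
  expect_message(d <- read_regression_csv(path, outcome = "y", weights = "wt"),
                 "dropped 1 incomplete row")
  expect_s3_class(d, "reg_dataset")
  expect_equal(d$n, 3L)
  expect_equal(d$n_dropped, 1L)
  expect_equal(d$feature_names, c("a", "b"))
  expect_equal(d$w, c(1, 2, 0.5))

  expect_error(read_regression_csv(path, outcome = "nope"), "outcome column")

  # zero / negative weights are invalid
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,y,wt", "1,2,0", "3,4,1"), bad)
  expect_error(read_regression_csv(bad, outcome = "y", weights = "wt"),
               "strictly positive")

  # write/read round trip preserves the dataset
  out <- withr::local_tempfile(fileext = ".csv")
  write_regression_csv(d, out)
  d2 <- read_regression_csv(out, outcome = "y", weights = ".weight")
  expect_equal(d2$y, d$y)
  expect_equal(d2$w, d$w)
  expect_equal(unname(d2$x), unname(d$x))
})

test_that("outcome summary matches hand computation and stats::quantile", {
  s <- outcome_summary(c(1, 1, 1, 1))
  expect_equal(s$variance, 0)
  expect_equal(s$range, 0)
  expect_equal(unname(s$icr[["25"]]), 0)

  expect_equal(outcome_summary(c(2, 7))$range, 5)

  s <- outcome_summary(0:10, centiles = 25)
  expect_equal(unname(s$icr[["25"]]), 5)  # p75 = 7.5, p25 = 2.5

  set.seed(11)
  y <- rnorm(57)
  for (X in c(5, 10, 25, 40)) {
    ref <- unname(quantile(y, 1 - X / 100, type = 7) -
                    quantile(y, X / 100, type = 7))
    expect_equal(unname(outcome_summary(y, X)$icr[[1]]), ref, tolerance = 1e-12)
  }
  expect_error(outcome_summary(numeric(0)), "non-empty")
})

test_that("dispersion statistics transform correctly under shift and scale", {
  set.seed(4)
  for (rep in 1:5) {
    y <- rnorm(40, sd = runif(1, 0.5, 3))
    s <- outcome_summary(y)
    # icr non-increasing in X and bounded by the range
    icrs <- vapply(c(5, 10, 25, 40, 49),
                   function(X) unname(outcome_summary(y, X)$icr[[1]]),
                   numeric(1))
    expect_true(all(diff(icrs) <= 1e-12))
    expect_true(all(icrs <= s$range + 1e-12))
    # shift invariance
    sh <- outcome_summary(y + 17.3)
    expect_equal(sh$variance, s$variance, tolerance = 1e-8)
    expect_equal(sh$range, s$range, tolerance = 1e-8)
    expect_equal(sh$icr, s$icr, tolerance = 1e-8)
    # scaling: variance by c^2, range/icr by |c|
    cc <- -2.5
    sc <- outcome_summary(cc * y)
    expect_equal(sc$variance, cc^2 * s$variance, tolerance = 1e-8)
    expect_equal(sc$range, abs(cc) * s$range, tolerance = 1e-8)
    expect_equal(unname(sc$icr), abs(cc) * unname(s$icr), tolerance = 1e-8)
  }
})

test_that("k-fold partitions are balanced, disjoint, exhaustive, seeded", {
  f <- kfold_indices(10, 10, seed = 3)
  expect_length(f, 10L)
  expect_true(all(lengths(f) == 1L))

  f <- kfold_indices(167, 10, seed = 5)
  expect_equal(sort(unname(lengths(f)), decreasing = TRUE),
               c(rep(17L, 7), rep(16L, 3)))
  expect_setequal(unlist(f), 1:167)
  expect_equal(sum(lengths(f)), 167L)

  expect_error(kfold_indices(5, 6), "k <= n")
  expect_identical(kfold_indices(50, 7, seed = 9), kfold_indices(50, 7, seed = 9))
  expect_false(identical(kfold_indices(50, 7, seed = 9),
                         kfold_indices(50, 7, seed = 10)))

  # caller RNG state is left untouched
  set.seed(123)
  before <- .Random.seed
  invisible(kfold_indices(30, 3, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("schema validation accepts matching pairs and rejects mismatches", {
  a <- gen_friedman1(20, seed = 1)
  b <- gen_friedman1(15, seed = 2)
  expect_silent(check_schema(a, b))
  b2 <- b
  b2$feature_names <- b2$feature_names[-1]
  expect_error(check_schema(a, b2), "differ")
})
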