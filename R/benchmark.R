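#' Reference benchmark MSPE table
#'
#' Previously reported minimum cross-validated MSPE values for five public
#' regression benchmarks (NHANES glycohemoglobin, Tasmanian Abalone, Boston
#' Housing crime rate, Los Angeles Ozone, MIT Servo) under each of the six
#' tree-growth limitation methods: parent-node size, leaf-node size, and the
#' variance, range, 10-90% and 25-75% intercentile-range proportions.
#' Shipped as plain CSV; useful as input to [relative_excess()] and as the
#' reference point for reproduction runs.
#'
#' @return Numeric matrix, rules in rows, datasets in columns.
#' @export
benchmark_mspe <- function() {
  path <- system.file("extdata", "benchmark_mspe.csv", package = "stoprf",
                      mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$rule
  m
}
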