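test_that("windowed imputation fills gaps from neighbours and is idempotent", {
  expect_equal(imputeMovingAverage(matrix(c(1, NA, 3), 3, 1)),
               matrix(c(1, 2, 3), 3, 1))
  # complete matrix: identity
  m <- matrix(rnorm(20), 5, 4)
  expect_identical(imputeMovingAverage(m), m)
  expect_identical(imputeMovingAverage(imputeMovingAverage(m)), m)
  # isolated missing run longer than the window falls back to the column mean
  col <- c(10, NA, NA, NA, 20)
  out <- imputeMovingAverage(matrix(col, 5, 1))
  expect_equal(out[3, 1], 15)  # whole window missing -> column mean
  expect_error(imputeMovingAverage(matrix(NA_real_, 4, 1)), "fully missing")
  expect_error(imputeMovingAverage(m, window = 4), "window")
})

test_that("windowed imputation matches the per-cell oracle on random matrices", {
  set.seed(33)
  for (rep in 1:4) {
    m <- matrix(rnorm(150), 30, 5)
    m[sample(length(m), 30)] <- NA
    if (any(colSums(!is.na(m)) == 0)) next
    expect_equal(imputeMovingAverage(m, 3), oracleWindowImpute(m, 3))
    expect_equal(imputeMovingAverage(m, 5), oracleWindowImpute(m, 5))
  }
})

test_that("normalizers produce their defining column statistics", {
  set.seed(21)
  m <- matrix(rexp(60, 1e-5), 12, 5)
  expect_equal(applyNormalizer(fitNormalizer(matrix(c(0, 5, 10), 3, 1),
                                             "minmax"),
                               matrix(c(0, 5, 10), 3, 1)),
               matrix(c(0, 0.5, 1), 3, 1))
  z <- applyNormalizer(fitNormalizer(m, "autoscale"), m)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(z, 2, colMeans(z))^2)) - 1) < 1e-9))
  # zscore is the same transform under the population-sd convention
  expect_equal(z, applyNormalizer(fitNormalizer(m, "zscore"), m))
  par <- applyNormalizer(fitNormalizer(m, "pareto"), m)
  expect_true(all(abs(colMeans(par)) < 1e-9))
  lg <- applyNormalizer(fitNormalizer(m, "log"), m)
  expect_equal(lg, log(m))  # areas >> 1, no offset engaged
  sq <- applyNormalizer(fitNormalizer(m, "sqrt"), m)
  expect_equal(sq, sqrt(m))
  expect_error(fitNormalizer(matrix(c(-1, 1), 2, 1), "log"), "non-negative")
})

test_that("pareto and autoscale agree on unit-variance features", {
  set.seed(4)
  m <- matrix(rnorm(40), 20, 2)
  popSd <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  m <- sweep(m, 2, popSd, "/")  # force population sd exactly 1
  expect_equal(applyNormalizer(fitNormalizer(m, "pareto"), m),
               applyNormalizer(fitNormalizer(m, "autoscale"), m))
})

test_that("quantile normalization equals the sort-average-restore oracle", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)
  z <- applyNormalizer(fitNormalizer(m, "quantile"), m)
  expect_equal(z[, 1], z[, 2])
  expect_equal(sort(z[, 1]), rowMeans(apply(m, 2, sort)))
  set.seed(12)
  r <- matrix(sample(1:8, 40, replace = TRUE), 8, 5)  # ties included
  zr <- applyNormalizer(fitNormalizer(r, "quantile"), r)
  expect_equal(zr, oracleQuantileNorm(r), ignore_attr = TRUE)
})

test_that("a fitted spec never leaks held-out statistics", {
  set.seed(90)
  train <- matrix(rnorm(50, 10, 2), 10, 5)
  test1 <- matrix(rnorm(25, 10, 2), 5, 5)
  test2 <- test1 + 100  # grossly shifted held-out data
  for (method in c("minmax", "autoscale", "pareto", "quantile")) {
    spec <- fitNormalizer(train, method)
    ztr1 <- applyNormalizer(spec, train)
    applyNormalizer(spec, test2)  # must not affect anything fitted
    expect_identical(applyNormalizer(spec, train), ztr1)
    # transform of test1 computed from train parameters only
    z1 <- applyNormalizer(spec, test1)
    spec2 <- fitNormalizer(train, method)  # refit: identical parameters
    expect_identical(applyNormalizer(spec2, test1), z1)
  }
  # constant features map to zero, not Inf
  cm <- cbind(rep(5, 8), rnorm(8))
  z <- applyNormalizer(fitNormalizer(cm, "autoscale"), cm)
  expect_true(all(z[, 1] == 0))
})

test_that("normalization specs survive the sidecar serialization", {
  set.seed(14)
  m <- matrix(rexp(30), 6, 5, dimnames = list(NULL, paste0("f", 1:5)))
  spec <- fitNormalizer(m, "autoscale")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeNormalizationSpec(spec, f)
  back <- readNormalizationSpec(f)
  expect_equal(applyNormalizer(back, m), applyNormalizer(spec, m))
})
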