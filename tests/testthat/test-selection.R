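test_that("exact rank-sum p-values match full enumeration", {
  res <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$W, 6)
  expect_equal(res$p, 0.1)  # 2 of the 20 assignments are as extreme
  set.seed(61)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxonRankSum(x, y, mode = "exact")$p,
                 oracleRankSumEnum(x, y))
  }
})

test_that("rank-sum agrees with the reference implementation", {
  set.seed(62)
  for (rep in 1:5) {
    x <- rnorm(15); y <- rnorm(12, 0.5)
    ours <- wilcoxonRankSum(x, y, mode = "normal")
    ref <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # W is the rank sum; the reference reports the Mann-Whitney U
    expect_equal(ours$W - length(x) * (length(x) + 1) / 2,
                 unname(ref$statistic))
  }
  # tied data engage the tie-corrected variance
  x <- c(1, 2, 2, 3, 5, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  expect_equal(wilcoxonRankSum(x, y)$p,
               suppressWarnings(wilcox.test(x, y, correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("rank-sum test has its defining symmetries and degeneracies", {
  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6, 5, 3.5)
  base <- wilcoxonRankSum(x, y)
  # invariance under strictly monotone transforms of the pooled data
  expect_equal(wilcoxonRankSum(exp(x), exp(y))$p, base$p)
  expect_equal(wilcoxonRankSum(log(x), log(y))$p, base$p)
  # label swap reflects W around its mean and keeps the two-sided p
  swap <- wilcoxonRankSum(y, x)
  n <- length(x) + length(y)
  expect_equal(base$W - length(x) * (n + 1) / 2,
               -(swap$W - length(y) * (n + 1) / 2))
  expect_equal(swap$p, base$p)
  # identical multisets carry no information
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(3, 1, 2), mode = "normal")$p, 1,
               tolerance = 0.2)
  deg <- wilcoxonRankSum(rep(2, 4), rep(2, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("exact and normal branches agree closely on tie-free 6+6 samples", {
  set.seed(63)
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.8)
    pe <- wilcoxonRankSum(x, y, mode = "exact")$p
    pn <- wilcoxonRankSum(x, y, mode = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("selection keeps significant features and preserves column order", {
  set.seed(64)
  v <- matrix(rnorm(60 * 20), 60, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  v[, 7] <- rep(0:1, each = 30)  # perfectly separated feature
  labels <- rep(c("CO", "CRC"), each = 30)
  sel <- selectFeatures(v, labels)
  expect_true("f07" %in% sel$selected)
  expect_false(sel$fallbackUsed)
  expect_identical(sel$table$feature, colnames(v))  # order preserved
  expect_identical(sel$table$direction[7], "CRC")
})

test_that("with nothing significant, the 13 highest-variance features are kept", {
  set.seed(400)
  v <- matrix(rnorm(20 * 40), 20, 40,
              dimnames = list(NULL, sprintf("f%02d", 1:40)))
  v <- sweep(v, 2, seq(0.5, 4, length.out = 40), "*")  # known variance order
  labels <- rep(c("CO", "CRC"), 10)
  sel <- selectFeatures(v, labels, alpha = 1e-6)  # null data: nothing passes
  expect_true(sel$fallbackUsed)
  expect_length(sel$selected, 13L)
  vars <- apply(v, 2, var)
  expect_setequal(sel$selected,
                  names(sort(vars, decreasing = TRUE))[1:13])
  # fallback ranking can come from the pre-scaling matrix
  z <- applyNormalizer(fitNormalizer(v, "autoscale"), v)
  sel2 <- selectFeatures(z, labels, alpha = 1e-6, varianceSource = v)
  expect_setequal(sel2$selected, sel$selected)
  expect_warning(selectFeatures(v[, 1:5], labels, alpha = 1e-6,
                                kFallback = 13), "capped")
})

test_that("selection on the planted simulation recovers the informative set", {
  cfg <- gcmsSimConfig(nCO = 200, nCRC = 200, noiseCV = 0.5,
                       missingRate = 0, seed = 19)
  ve <- simulateGcms(cfg)
  sel <- selectFeatures(vocMatrix(ve), classLabels(ve))
  expect_true(all(defaultInformativeFeatures()$rt %in% sel$selected))
})
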