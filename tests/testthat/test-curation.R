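test_that("rounding groups redundant peaks and merges by the chosen rule", {
  pt <- peakTable("a", rt = c(10.68, 10.74), area = c(100, 50))
  merged <- roundAndMerge(pt)
  expect_equal(merged@peaks, data.frame(rt = 10.7, area = 150))
  expect_equal(roundAndMerge(pt, mergeRule = "max")@peaks$area, 100)
  # a single already-rounded peak is untouched
  expect_equal(roundAndMerge(peakTable("b", 10.7, 5))@peaks,
               data.frame(rt = 10.7, area = 5))
})

test_that("round-and-merge matches the dictionary-accumulation oracle and conserves area", {
  set.seed(101)
  for (rep in 1:5) {
    rt <- runif(50, 1, 29)
    area <- rexp(50, 1e-6)
    pt <- roundAndMerge(peakTable("s", rt, area))
    orc <- oracleRoundMerge(rt, area)
    expect_equal(pt@peaks$rt, orc$rt)
    expect_equal(pt@peaks$area, orc$area)
    expect_equal(sum(pt@peaks$area), sum(area))          # sum rule conserves
    expect_false(is.unsorted(pt@peaks$rt, strictly = TRUE))
  }
})

test_that("consolidation takes the union of RTs with missing (not zero) gaps", {
  t1 <- peakTable("s1", 10.7, 1)
  t2 <- peakTable("s2", 10.8, 2)
  ve <- consolidatePeakTables(list(t1, t2), c("CO", "CRC"))
  v <- vocMatrix(ve)
  expect_identical(dim(v), c(2L, 2L))
  expect_identical(colnames(v), c("10.7", "10.8"))
  expect_equal(unname(v), matrix(c(1, NA, NA, 2), 2, 2))
  expect_error(consolidatePeakTables(list(t1, t1), c("CO", "CRC")),
               "duplicate sample_id")
})

test_that("consolidate and split are mutually inverse", {
  set.seed(7)
  tabs <- lapply(1:6, function(i)
    roundAndMerge(peakTable(paste0("s", i), runif(30, 1, 29), rexp(30))))
  ve <- consolidatePeakTables(tabs, rep(c("CO", "CRC"), 3))
  back <- consolidatePeakTables(splitPeakTables(ve),
                                as.character(classLabels(ve)))
  expect_identical(vocMatrix(back), vocMatrix(ve))
  # single-table identity: the row equals the merged areas
  one <- consolidatePeakTables(tabs[1], "CO")
  expect_equal(unname(vocMatrix(one)[1, ]), tabs[[1]]@peaks$area)
})

test_that("empty features are dropped exactly as planted", {
  set.seed(8)
  v <- matrix(rexp(80), 10, 8,
              dimnames = list(NULL, sprintf("%0.1f", 1:8)))
  planted <- c(2, 5, 7)
  v[, 2] <- NA            # fully missing
  v[, 5] <- 0             # all-zero counts as no signal
  v[, 7] <- c(NA, 0)[c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)]
  ve <- VocExperiment(v, rep(c("CO", "CRC"), 5))
  out <- dropEmptyFeatures(ve)
  expect_identical(colnames(vocMatrix(out)), colnames(v)[-planted])
  # one positive entry is enough at minPresent = 1
  v2 <- v; v2[1, 2] <- 3.5
  out2 <- dropEmptyFeatures(VocExperiment(v2, rep(c("CO", "CRC"), 5)))
  expect_true("2.0" %in% colnames(vocMatrix(out2)))
  expect_error(dropEmptyFeatures(
    VocExperiment(matrix(NA_real_, 3, 2), c("CO", "CO", "CRC"))),
    "all features removed")
})

test_that("internal-standard normalization scales rows and is invariant to joint scaling", {
  v <- matrix(c(2, 4, 6, 8), 2, 2)
  ve <- VocExperiment(v, c("CO", "CRC"), sampleIds = c("a", "b"))
  out <- normalizeToInternalStandard(ve, c(a = 2, b = 1))
  expect_equal(unname(vocMatrix(out)), rbind(c(1, 3), c(4, 8)))
  # IS = 1 for all samples is the identity
  expect_equal(vocMatrix(normalizeToInternalStandard(ve, c(a = 1, b = 1))),
               vocMatrix(ve))
  # scaling one sample's areas and IS by the same factor changes nothing
  v2 <- v; v2[1, ] <- v2[1, ] * 7
  out2 <- normalizeToInternalStandard(
    VocExperiment(v2, c("CO", "CRC"), sampleIds = c("a", "b")),
    c(a = 14, b = 1))
  expect_equal(vocMatrix(out2)[1, ], vocMatrix(out)[1, ])
  expect_error(normalizeToInternalStandard(ve, c(a = 2, b = 0)), "b")
})

test_that("peak tables round-trip through their CSV layout", {
  pt <- peakTable("sw01", rt = c(6.1, 10.7), area = c(1e5, 2e6), isArea = 321)
  f <- withr::local_tempfile(fileext = ".csv")
  writePeakTable(pt, f)
  back <- readPeakTable(f)
  expect_equal(back@peaks, pt@peaks)
  expect_identical(back@sampleId, "sw01")
  expect_equal(back@isArea, 321)
})
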