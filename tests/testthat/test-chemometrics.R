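## --- PCA ---------------------------------------------------------------

test_that("PCA recovers a one-dimensional structure and reconstructs exactly", {
  x <- cbind(1:10, 1:10)  # points on the line y = x
  m <- fitPCA(x, 2)
  expect_equal(m@varRatio, c(1, 0), tolerance = 1e-12)
  set.seed(71)
  r <- matrix(rnorm(120), 20, 6)
  full <- fitPCA(r, 6)
  centered <- sweep(r, 2, colMeans(r))
  expect_equal(full@scores %*% t(full@loadings), centered,
               tolerance = 1e-8, ignore_attr = TRUE)
  # scores are uncorrelated
  cc <- crossprod(sweep(full@scores, 2, colMeans(full@scores)))
  expect_true(max(abs(cc[upper.tri(cc)])) < 1e-8)
  expect_error(fitPCA(matrix(1, 5, 3), 2), "constant")
})

test_that("PCA eigenvalues match an independent eigensolver and prcomp", {
  set.seed(72)
  x <- matrix(rnorm(120), 20, 6)
  m <- fitPCA(x, 5)
  ev <- oracleEigenPCA(x)$values
  sv2 <- apply(m@scores, 2, function(s) sum(s^2)) / (nrow(x) - 1)
  expect_equal(unname(sv2), ev[1:5], tolerance = 1e-8)
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  expect_equal(abs(unname(m@loadings)), abs(unname(pr$rotation[, 1:5])),
               tolerance = 1e-8)
  # held-out projection reproduces training scores
  expect_equal(projectPCA(m, x), m@scores, ignore_attr = TRUE)
})

## --- PLS-DA ------------------------------------------------------------

test_that("PLS-DA handles the degenerate single-feature geometries", {
  y <- rep(c("CO", "CRC"), each = 6)
  xEq <- cbind(as.numeric(y == "CRC"), rnorm(12, 0, 1e-8))
  m <- fitPLSDA(xEq, y, nLV = 1)
  expect_gt(m@yVarRatio[1], 1 - 1e-6)  # one LV explains all of Y
  # X orthogonal to y: no explained Y variance on the first LV
  set.seed(73)
  xo <- matrix(rnorm(24), 12, 2)
  yc <- as.numeric(y == "CRC") - 0.5
  xo <- xo - yc %*% t(drop(crossprod(xo, yc)) / sum(yc^2))
  mo <- fitPLSDA(xo, y, nLV = 1)
  expect_lt(abs(mo@yLoadings[1]), 1e-8)
  expect_lt(mo@yVarRatio[1], 1e-12)
})

test_that("the first PLS weight equals the dominant eigenvector of X'y y'X", {
  set.seed(74)
  x <- matrix(rnorm(48), 12, 4)
  y <- rep(c("CO", "CRC"), 6)
  m <- fitPLSDA(x, y, nLV = 1)
  yc <- as.numeric(y == "CRC"); yc <- yc - mean(yc)
  xc <- sweep(x, 2, colMeans(x))
  M <- tcrossprod(crossprod(xc, yc))  # X'y y'X
  e1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(unname(m@weights[, 1])), abs(e1), tolerance = 1e-8)
})

test_that("X-scores are orthogonal and projection matches training scores", {
  set.seed(75)
  x <- matrix(rnorm(200), 20, 10)
  y <- rep(c("CO", "CRC"), 10)
  m <- fitPLSDA(x, y, nLV = 3)
  G <- crossprod(m@scores)
  nrm <- sqrt(diag(G))
  expect_true(all(abs(G[upper.tri(G)]) <
                    1e-8 * tcrossprod(nrm)[upper.tri(G)]))
  expect_equal(plsProject(m, x), m@scores, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("full-rank PLS reproduces least-squares predictions of the class code", {
  set.seed(76)
  x <- matrix(rnorm(60), 15, 4)
  y <- rep(c("CO", "CRC"), c(8, 7))
  m <- suppressWarnings(fitPLSDA(x, y, nLV = 4))
  yhatPls <- plsPredict(m, x)
  yc <- as.numeric(y == "CRC")
  yhatOls <- fitted(lm(yc ~ x))
  expect_equal(unname(yhatPls), unname(yhatOls), tolerance = 1e-6)
})

test_that("requesting more latent variables than the rank truncates with a warning", {
  x <- cbind(1:12, (1:12) * 2)  # rank 1 after centering
  y <- rep(c("CO", "CRC"), 6)
  expect_warning(m <- fitPLSDA(x, y, nLV = 3), "truncated")
  expect_lte(ncol(m@weights), 2L)
})

## --- VIP ---------------------------------------------------------------

test_that("VIP scores follow the closed-form for one latent variable", {
  set.seed(77)
  # equal weights give unit VIPs; w = (0.6, 0.8) gives sqrt(0.72), sqrt(1.28)
  y <- rep(c("CO", "CRC"), each = 10)
  makeModel <- function(w) {
    # build data whose single PLS weight is exactly w
    t <- as.numeric(y == "CRC") - 0.5 + rnorm(20, 0, 1e-9)
    x <- t %*% t(w)
    fitPLSDA(x, y, nLV = 1)
  }
  m1 <- makeModel(c(1, 1) / sqrt(2))
  expect_equal(unname(vipScores(m1)), c(1, 1), tolerance = 1e-6)
  m2 <- makeModel(c(0.6, 0.8))
  expect_equal(unname(vipScores(m2)), c(sqrt(0.72), sqrt(1.28)),
               tolerance = 1e-6)
})

test_that("squared VIPs always sum to the number of features", {
  set.seed(78)
  for (rep in 1:5) {
    p <- sample(4:30, 1)
    x <- matrix(rnorm(40 * p), 40, p)
    y <- rep(c("CO", "CRC"), 20)
    m <- fitPLSDA(x, y, nLV = 3)
    expect_equal(sum(vipScores(m)^2), p, tolerance = 1e-6 * p)
  }
})

test_that("VIP ranking is invariant to pre-autoscaling feature rescaling", {
  set.seed(79)
  ve <- simulateGcms(gcmsSimConfig(nCO = 30, nCRC = 30, nFeatures = 40,
                                   informative = informativeOnGrid(4, 40),
                                   missingRate = 0, seed = 80))
  v <- vocMatrix(ve)
  labels <- classLabels(ve)
  pipelineVip <- function(x) {
    z <- applyNormalizer(fitNormalizer(x, "autoscale"), x)
    rank(-vipScores(fitPLSDA(z, labels, nLV = 3)))
  }
  scale <- rep(c(1e-3, 50), length.out = ncol(v))
  expect_equal(pipelineVip(v), pipelineVip(sweep(v, 2, scale, "*")),
               ignore_attr = TRUE)
})

test_that("planted informative features attain top VIP ranks", {
  ranks <- sapply(1:8, function(s) {
    ve <- simulateGcms(gcmsSimConfig(nCO = 60, nCRC = 60, missingRate = 0,
                                     seed = 300 + s))
    v <- vocMatrix(ve)
    z <- applyNormalizer(fitNormalizer(v, "autoscale"), v)
    vip <- vipScores(fitPLSDA(z, classLabels(ve), nLV = 3))
    median(rank(-vip)[defaultInformativeFeatures()$rt])
  })
  expect_lte(median(ranks), 15)
})

## --- OSC ---------------------------------------------------------------

test_that("OSC removes only class-orthogonal structure", {
  set.seed(81)
  x <- matrix(rnorm(200), 20, 10)
  y <- rep(c("CO", "CRC"), 10)
  expect_identical(oscCorrect(x, y, nOsc = 0)$corrected, x)
  res <- oscCorrect(x, y, nOsc = 2)
  expect_true(all(res$model@scoreYCor < 1e-6))
  # removed scores are exactly orthogonal to the centered class code
  yc <- as.numeric(y == "CRC"); yc <- yc - mean(yc)
  for (a in seq_len(ncol(res$model@scores)))
    expect_lt(abs(cor(res$model@scores[, a], yc)), 1e-6)
})

test_that("OSC is a near-identity when X has no class-orthogonal structure", {
  y <- rep(c("CO", "CRC"), each = 10)
  yc <- as.numeric(y == "CRC") - 0.5
  x <- yc %*% t(c(3, -1, 2)) + 5  # pure class signal
  res <- oscCorrect(x, y, nOsc = 1)
  expect_lt(norm(res$corrected - x, "F") / norm(x, "F"), 1e-6)
})

test_that("OSC weights transfer to held-out data without labels", {
  set.seed(82)
  cfg <- enoseSimConfig(seed = 83)
  fm <- buildEnoseMatrix(simulateEnose(cfg))
  x <- vocMatrix(fm); y <- classLabels(fm)
  res <- oscCorrect(x, y, nOsc = 1)
  z <- oscApply(res$model, x)
  expect_identical(dim(z), dim(x))
  # applying to the training data removes the same dominant direction:
  # the removed-score correlation between the two routes is ~1
  tTrain <- res$model@scores[, 1]
  tApply <- drop(sweep(x, 2, res$model@center) %*% res$model@weights[, 1])
  expect_gt(abs(cor(tTrain, tApply)), 0.99)
})

## --- PERMANOVA ---------------------------------------------------------

test_that("PERMANOVA pseudo-F matches the independent implementations", {
  set.seed(84)
  x <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 1), 10))
  labels <- rep(c("CO", "CRC"), each = 10)
  res <- permanovaTest(x, labels, nPerm = 99, seed = 1)
  expect_equal(res$statistic, oraclePermanovaF(x, labels), tolerance = 1e-10)
  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(dist(x) ~ g, data = data.frame(g = labels),
                       permutations = 49)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-8)
})

test_that("identical group point-sets give no separation", {
  x <- rbind(diag(3), diag(3))
  res <- permanovaTest(x, rep(c("CO", "CRC"), each = 3), nPerm = 99, seed = 2)
  expect_gt(res$p.value, 0.9)
})

test_that("the 3+3 permutation distribution equals full enumeration", {
  set.seed(85)
  x <- matrix(rnorm(12), 6, 2)
  labels <- rep(c("CO", "CRC"), each = 3)
  enum <- oraclePermanovaEnum(x, labels)
  obs <- oraclePermanovaF(x, labels)
  pExact <- mean(enum >= obs - 1e-12)
  res <- permanovaTest(x, labels, nPerm = 1999, seed = 3)
  expect_equal(res$p.value, pExact, tolerance = 0.05)
  expect_error(permanovaTest(x, c("CO", rep("CRC", 5)), seed = 1),
               "at least 2")
})
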