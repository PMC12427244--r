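test_that("stratified folds balance both classes to within one sample", {
  labels <- rep(c("CO", "CRC"), c(34, 31))
  folds <- stratifiedKFold(labels, 5, seed = 1)
  tab <- table(folds, labels)
  expect_true(all(table(folds) == 13))       # 65 = 5 x 13
  expect_true(all(tab[, "CO"] %in% 6:7))     # 34 = 5*6 + 4
  expect_true(all(tab[, "CRC"] %in% 6:7))    # 31 = 5*6 + 1
  expect_identical(folds, stratifiedKFold(labels, 5, seed = 1))
  f2 <- stratifiedKFold(labels, 5, seed = 2)
  expect_false(identical(folds, f2))
  tab2 <- table(f2, labels)
  expect_true(all(abs(outer(tab2[, 1], tab2[, 1], "-")) <= 1))
  expect_error(stratifiedKFold(labels, 1), "k")
  expect_error(stratifiedKFold(c("CO", "CO", "CRC"), 2), "smaller than k")
})

test_that("k-NN votes among true neighbours and applies its tie rules", {
  train <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  trainY <- rep(c("CO", "CRC"), each = 5)
  out <- knnClassify(train, trainY, matrix(c(0, 0, 10, 10), 2, 2,
                                           byrow = TRUE), k = 5)
  expect_identical(as.character(out$pred), c("CO", "CRC"))
  expect_equal(out$score, c(0, 1))
  # equal-distance straddle at even k: smaller mean distance, then CO
  tr <- matrix(c(-1, -1, 1, 1), 4, 1)
  expect_warning(
    tie <- knnClassify(tr, c("CO", "CRC", "CO", "CRC"), matrix(0, 1, 1),
                       k = 2),
    "even")
  expect_identical(as.character(tie$pred), "CO")
})

test_that("k-NN predictions equal the brute-force all-pairs oracle", {
  set.seed(95)
  train <- matrix(rnorm(120), 40, 3)
  trainY <- rep(c("CO", "CRC"), 20)
  test <- matrix(rnorm(45), 15, 3)
  ours <- knnClassify(train, trainY, test, k = 5)
  expect_identical(as.character(ours$pred), oracleKnn(train, trainY, test, 5))
})

test_that("LDA separates spherical Gaussians along the mean difference", {
  set.seed(96)
  x <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, 6), 50))
  y <- rep(c("CO", "CRC"), each = 50)
  out <- ldaClassify(x, y, x)
  expect_identical(as.character(out$pred), as.character(y))
  # identical class means: held-out predictions are prior-driven noise
  xn <- matrix(rnorm(200), 100, 2)
  outn <- ldaClassify(xn[1:60, ], y[c(1:30, 51:80)], xn[61:100, ])
  expect_true(mean(as.character(outn$pred) ==
                     y[c(31:50, 81:100)]) < 0.8)
})

test_that("the LDA discriminant direction matches the hand-inverted solution", {
  set.seed(97)
  x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 1.5), 30, 2))
  y <- rep(c("CO", "CRC"), each = 30)
  wOracle <- oracleLda2d(x, y)
  # recover the implementation's direction from two probe scores
  probes <- ldaClassify(x, y, rbind(c(1, 0), c(0, 1), c(0, 0)),
                        shrinkage = 0)$score
  wOurs <- probes[1:2] - probes[3]
  expect_equal(wOurs, wOracle, tolerance = 1e-8)
  skip_if_not_installed("MASS")
  fit <- MASS::lda(x, grouping = y)
  dir <- drop(fit$scaling)
  expect_equal(abs(wOurs / sqrt(sum(wOurs^2))), abs(dir / sqrt(sum(dir^2))),
               tolerance = 1e-6)
})

test_that("penalized logistic regression matches an independent optimizer", {
  set.seed(98)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("CO", "CRC"), 10)
  ours <- logregClassify(x, y, x, l2 = 1)
  ref <- oracleRidgeLogreg(x, as.numeric(y == "CRC"), l2 = 1)
  expect_equal(unname(ours$coef), ref, tolerance = 1e-4)
  # perfectly separable data still converge to finite weights
  xs <- matrix(c(rep(-2, 10), rep(2, 10)), 20, 1)
  sep <- logregClassify(xs, y[order(y)], xs, l2 = 1)
  expect_true(all(is.finite(sep$coef)))
  expect_identical(as.character(sep$pred), sort(as.character(y)))
})

test_that("the linear SVM finds a separating hyperplane and respects the margin", {
  set.seed(99)
  x <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c("CO", "CRC"), each = 30)
  out <- svmClassify(x, y, x, C = 1)
  expect_identical(as.character(out$pred), as.character(y))
  skip_if_not_installed("e1071")
  ref <- e1071::svm(x, factor(y), kernel = "linear", cost = 1, scale = FALSE)
  refDec <- drop(attr(predict(ref, x, decision.values = TRUE),
                      "decision.values"))
  sgn <- if (cor(refDec, out$score) < 0) -1 else 1
  expect_gt(cor(sgn * refDec, out$score), 0.99)
})

test_that("classifiers stay at chance when labels are independent of features", {
  y <- rep(c("CO", "CRC"), 30)
  for (clf in c("lda", "lr", "svm", "knn")) {
    accs <- sapply(1:5, function(s) {
      set.seed(1000 + s)
      x <- matrix(rnorm(60 * 4), 60, 4)
      cvAccuracy(crossValidate(x, y, clf, folds = 5, seed = s,
                               classifierArgs = if (clf == "knn") list(k = 5)
                                                else list()))
    })
    expect_lt(mean(accs), 62)  # chance plus Monte-Carlo noise
    expect_gt(mean(accs), 38)
  }
})
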