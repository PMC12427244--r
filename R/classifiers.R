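## ---------------------------------------------------------------------------
## From-scratch linear classifiers and stratified cross-validation folds.
## Every classifier follows one contract: (trainX, trainY, testX, ...) ->
## list(pred = factor CO/CRC, score = numeric, higher = more CRC-like).
## ---------------------------------------------------------------------------

#' Stratified k-fold assignments
#'
#' Shuffles each class separately (seeded) and deals samples round-robin
#' into `k` folds, so per-class fold counts differ by at most one.
#'
#' @param labels class labels.
#' @param k number of folds (default 5, must be >= 2).
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @examples
#' table(stratifiedKFold(rep(c("CO", "CRC"), c(34, 31)), 5, seed = 1),
#'       rep(c("CO", "CRC"), c(34, 31)))
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = NULL) {
  labels <- factor(labels)
  stopifnot(k >= 2)
  sizes <- table(labels)
  if (any(sizes < k))
    stop("class smaller than k: ", paste(names(sizes)[sizes < k], collapse = ", "))
  folds <- integer(length(labels))
  withSeed(seed, {
    offset <- 0L  # rotate the round-robin start so fold totals stay even
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

## score -> prediction at a fixed threshold
.scoreToPred <- function(score, threshold = 0) {
  factor(ifelse(score > threshold, "CRC", "CO"), levels = .vocClasses)
}

#' k-nearest-neighbour classifier
#'
#' Euclidean distances, majority vote among the `k` nearest training
#' samples. Vote ties are broken in favour of the class with the smaller
#' mean distance among the tied neighbours, then for the negative class
#' (CO). The score is the CRC vote fraction.
#'
#' @param trainX,trainY training matrix and labels.
#' @param testX test matrix (same features).
#' @param k number of neighbours (default 5); an even `k` warns since votes
#'   can tie.
#' @return list with `pred` (factor) and `score` (CRC votes / k).
#' @export
knnClassify <- function(trainX, trainY, testX, k = 5L) {
  trainY <- .asVocFactor(trainY)
  stopifnot(nrow(trainX) == length(trainY), k >= 1, k <= nrow(trainX))
  if (k %% 2 == 0) warning("even k: vote ties possible")
  testX <- rbind(testX)
  nTest <- nrow(testX)
  pred <- character(nTest)
  score <- numeric(nTest)
  for (i in seq_len(nTest)) {
    d <- sqrt(colSums((t(trainX) - testX[i, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(trainY[nn])
    score[i] <- votes[["CRC"]] / k
    if (votes[["CRC"]] != votes[["CO"]]) {
      pred[i] <- names(votes)[which.max(votes)]
    } else {
      mdCO <- mean(d[nn][trainY[nn] == "CO"])
      mdCRC <- mean(d[nn][trainY[nn] == "CRC"])
      pred[i] <- if (mdCRC < mdCO) "CRC" else "CO"
    }
  }
  list(pred = factor(pred, levels = .vocClasses), score = score)
}

#' Linear discriminant analysis classifier
#'
#' Gaussian equal-covariance (Fisher) rule: the discriminant direction is
#' `S_w^{-1} (mu_CRC - mu_CO)` with the pooled within-class covariance
#' ridge-regularized by `shrinkage * I`. Scores are posterior log-odds for
#' CRC including the log prior ratio; threshold 0.
#'
#' @param trainX,trainY training matrix and labels.
#' @param testX test matrix.
#' @param shrinkage ridge added to the pooled covariance diagonal
#'   (default 1e-6, scaled by the mean diagonal).
#' @return list with `pred` and `score` (log-odds).
#' @export
ldaClassify <- function(trainX, trainY, testX, shrinkage = 1e-6) {
  trainY <- .asVocFactor(trainY)
  stopifnot(nrow(trainX) == length(trainY))
  testX <- rbind(testX)
  isCrc <- trainY == "CRC"
  stopifnot(sum(isCrc) >= 2, sum(!isCrc) >= 2)
  mu0 <- colMeans(trainX[!isCrc, , drop = FALSE])
  mu1 <- colMeans(trainX[isCrc, , drop = FALSE])
  n <- nrow(trainX)
  c0 <- sweep(trainX[!isCrc, , drop = FALSE], 2, mu0)
  c1 <- sweep(trainX[isCrc, , drop = FALSE], 2, mu1)
  Sw <- (crossprod(c0) + crossprod(c1)) / (n - 2)
  ridge <- shrinkage * mean(diag(Sw))
  if (ridge <= 0) ridge <- shrinkage
  Sw <- Sw + diag(ridge, ncol(Sw))
  w <- tryCatch(solve(Sw, mu1 - mu0),
                error = function(e)
                  stop("singular within-class covariance; increase shrinkage ",
                       "or reduce dimension with PCA first"))
  prior <- log(mean(isCrc) / mean(!isCrc))
  score <- drop(testX %*% w) - drop(crossprod((mu0 + mu1) / 2, w)) + prior
  list(pred = .scoreToPred(score), score = score)
}

#' L2-penalized logistic regression classifier
#'
#' Minimizes the log-loss plus `l2/2 * ||beta||^2` (intercept unpenalized)
#' by iteratively reweighted least squares, to gradient norm below `tol`.
#' Scores are the linear predictor (log-odds); threshold 0.
#'
#' @param trainX,trainY training matrix and labels.
#' @param testX test matrix.
#' @param l2 ridge penalty (default 1).
#' @param tol gradient-norm convergence tolerance (default 1e-6).
#' @param maxIter iteration cap (default 100).
#' @return list with `pred`, `score`, and the fitted `coef` (intercept
#'   first).
#' @export
logregClassify <- function(trainX, trainY, testX, l2 = 1.0, tol = 1e-6,
                           maxIter = 100L) {
  trainY <- .asVocFactor(trainY)
  stopifnot(nrow(trainX) == length(trainY))
  testX <- rbind(testX)
  X <- cbind(1, trainX)
  y <- as.numeric(trainY == "CRC")
  pDim <- ncol(X)
  beta <- numeric(pDim)
  pen <- c(0, rep(l2, pDim - 1L))
  gnorm <- Inf
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, mu - y)) + pen * beta
    gnorm <- sqrt(sum(grad^2))
    if (gnorm < tol) break
    wts <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * wts, X) + diag(pen, pDim)
    beta <- beta - solve(H, grad)
  }
  if (gnorm >= tol)
    stop(sprintf("logistic regression did not converge (gradient norm %.3g)",
                 gnorm))
  score <- drop(cbind(1, testX) %*% beta)
  list(pred = .scoreToPred(score), score = score, coef = beta)
}

#' Linear support-vector machine classifier
#'
#' L2-regularized hinge loss, `min 0.5 ||w||^2 + C sum hinge`, solved in the
#' dual by coordinate descent over the box-constrained alphas (bias handled
#' through an augmented constant feature). Deterministic sweep order;
#' convergence when the maximum projected-gradient violation falls below
#' `tol`. Scores are the signed decision values `w'x + b`; threshold 0.
#'
#' @param trainX,trainY training matrix and labels.
#' @param testX test matrix.
#' @param C hinge-loss cost (default 1).
#' @param tol projected-gradient tolerance (default 1e-4).
#' @param maxIter sweep cap (default 2000).
#' @return list with `pred`, `score`, `w`, `b`.
#' @export
svmClassify <- function(trainX, trainY, testX, C = 1.0, tol = 1e-4,
                        maxIter = 2000L) {
  trainY <- .asVocFactor(trainY)
  stopifnot(nrow(trainX) == length(trainY))
  testX <- rbind(testX)
  X <- cbind(trainX, 1)  # augmented bias feature
  y <- ifelse(trainY == "CRC", 1, -1)
  n <- nrow(X)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  Q <- rowSums(X^2)
  converged <- FALSE
  for (sweepIt in seq_len(maxIter)) {
    maxViol <- 0
    for (i in seq_len(n)) {
      G <- y[i] * sum(w * X[i, ]) - 1
      PG <- if (alpha[i] <= 0) min(G, 0)
            else if (alpha[i] >= C) max(G, 0)
            else G
      maxViol <- max(maxViol, abs(PG))
      if (abs(PG) > 1e-12) {
        aOld <- alpha[i]
        alpha[i] <- min(max(alpha[i] - G / Q[i], 0), C)
        w <- w + (alpha[i] - aOld) * y[i] * X[i, ]
      }
    }
    if (maxViol < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("SVM did not converge within %d sweeps", maxIter))
  score <- drop(cbind(testX, 1) %*% w)
  list(pred = .scoreToPred(score), score = score,
       w = w[-length(w)], b = w[length(w)])
}

## registry used by the CV engine and the pipelines
.classifierFuns <- function(name, args = list()) {
  f <- switch(name,
    knn = function(trX, trY, teX) do.call(knnClassify,
                                          c(list(trX, trY, teX), args)),
    lda = function(trX, trY, teX) do.call(ldaClassify,
                                          c(list(trX, trY, teX), args)),
    lr = function(trX, trY, teX) do.call(logregClassify,
                                         c(list(trX, trY, teX), args)),
    svm = function(trX, trY, teX) do.call(svmClassify,
                                          c(list(trX, trY, teX), args)),
    stop("unknown classifier: ", name))
  f
}
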