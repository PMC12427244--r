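# Brute-force oracles used to cross-check the implementation.
# Each is an independent, naive computation sharing no code with the package.

# dictionary accumulation of peak areas keyed on the formatted rounded RT
oracleRoundMerge <- function(rt, area, decimals = 1, rule = "sum") {
  m <- 10^decimals
  key <- sprintf(paste0("%.", decimals, "f"),
                 sign(rt) * floor(abs(rt) * m + 0.5) / m)
  acc <- list()
  for (i in seq_along(rt)) {
    k <- key[i]
    acc[[k]] <- if (is.null(acc[[k]])) area[i]
                else if (rule == "sum") acc[[k]] + area[i]
                else max(acc[[k]], area[i])
  }
  ord <- order(as.numeric(names(acc)))
  data.frame(rt = as.numeric(names(acc))[ord],
             area = unlist(acc, use.names = FALSE)[ord])
}

# per-cell centered windowed mean over rows of the same column
oracleWindowImpute <- function(x, window = 3) {
  half <- (window - 1) / 2
  out <- x
  for (j in seq_len(ncol(x))) for (i in seq_len(nrow(x))) {
    if (is.na(x[i, j])) {
      lo <- max(1, i - half); hi <- min(nrow(x), i + half)
      vals <- x[lo:hi, j]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals) > 0) mean(vals)
                   else mean(x[, j], na.rm = TRUE)
    }
  }
  out
}

# Bolstad-style quantile normalization: sort each column, average across
# columns per rank, restore by rank (midrank ties get the mean of the
# implied reference values)
oracleQuantileNorm <- function(x) {
  srt <- apply(x, 2, sort)
  ref <- rowMeans(srt)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- sapply(r, function(ri) {
      if (ri == floor(ri)) ref[ri]
      else mean(ref[c(floor(ri), ceiling(ri))])
    })
  }
  out
}

# exact two-sided rank-sum p by full enumeration of group assignments
oracleRankSumEnum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  obs <- sum(r[seq_len(nx)])
  mu <- nx * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# PCA eigenvalues via a dense eigendecomposition of the covariance matrix
oracleEigenPCA <- function(x) {
  eigen(stats::cov(x), symmetric = TRUE)
}

# all-pairs-distance k-NN with the package's documented tie rules,
# recomputed naively
oracleKnn <- function(trainX, trainY, testX, k) {
  pred <- character(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- apply(trainX, 1, function(r) sqrt(sum((r - testX[i, ])^2)))
    nn <- order(d)[1:k]
    nCrc <- sum(trainY[nn] == "CRC")
    nCo <- k - nCrc
    pred[i] <- if (nCrc > nCo) "CRC"
      else if (nCo > nCrc) "CO"
      else {
        mCrc <- mean(d[nn][trainY[nn] == "CRC"])
        mCo <- mean(d[nn][trainY[nn] == "CO"])
        if (mCrc < mCo) "CRC" else "CO"
      }
  }
  pred
}

# AUC by pair counting: (wins + half-ties) / (n_pos * n_neg)
oracleAucPairs <- function(truth, scores) {
  pos <- scores[truth == "CRC"]
  neg <- scores[truth == "CO"]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# PERMANOVA pseudo-F recomputed from scratch for one labeling
oraclePermanovaF <- function(x, labels) {
  d2 <- as.matrix(dist(x))^2
  n <- nrow(x)
  ssT <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (l in unique(labels)) {
    i <- which(labels == l)
    dk <- d2[i, i, drop = FALSE]
    ssW <- ssW + sum(dk[upper.tri(dk)]) / length(i)
  }
  g <- length(unique(labels))
  ((ssT - ssW) / (g - 1)) / (ssW / (n - g))
}

# full enumeration of the PERMANOVA permutation distribution (small n)
oraclePermanovaEnum <- function(x, labels) {
  n <- nrow(x)
  nA <- sum(labels == labels[1])
  idx <- utils::combn(n, nA)
  apply(idx, 2, function(i) {
    lab <- rep("B", n)
    lab[i] <- "A"
    oraclePermanovaF(x, lab)
  })
}

# LDA discriminant direction via a hand-coded 2x2 matrix inverse
oracleLda2d <- function(x, labels) {
  x0 <- x[labels == "CO", , drop = FALSE]
  x1 <- x[labels == "CRC", , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  Sw <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) /
    (nrow(x) - 2)
  det <- Sw[1, 1] * Sw[2, 2] - Sw[1, 2] * Sw[2, 1]
  inv <- matrix(c(Sw[2, 2], -Sw[2, 1], -Sw[1, 2], Sw[1, 1]), 2, 2) / det
  drop(inv %*% (mu1 - mu0))
}

# metric panel recomputed directly from the four counts
oracleMetricsFromCounts <- function(tn, fp, fn, tp) {
  list(accuracy = 100 * (tn + tp) / (tn + fp + fn + tp),
       sensCRC = 100 * tp / (tp + fn), sensCO = 100 * tn / (tn + fp),
       specCRC = 100 * tn / (tn + fp), specCO = 100 * tp / (tp + fn),
       precCRC = 100 * tp / (tp + fp), precCO = 100 * tn / (tn + fn),
       f1CRC = 100 * 2 * tp / (2 * tp + fp + fn),
       f1CO = 100 * 2 * tn / (2 * tn + fn + fp),
       fpRate = 100 * fp / (tn + fp), fnRate = 100 * fn / (tp + fn))
}

# independent penalized-likelihood optimizer for ridge logistic regression
oracleRidgeLogreg <- function(X, y, l2) {
  nll <- function(b) {
    eta <- drop(cbind(1, X) %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + l2 / 2 * sum(b[-1]^2)
  }
  stats::optim(rep(0, ncol(X) + 1), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}
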