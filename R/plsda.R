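## ---------------------------------------------------------------------------
## NIPALS PLS1 discriminant analysis with VIP scores
## ---------------------------------------------------------------------------

#' Fit a PLS-DA model (NIPALS PLS1)
#'
#' The class membership is coded 0 (CO) / 1 (CRC) and centered; per latent
#' variable the algorithm takes `w = X'y / ||X'y||`, `t = X w`,
#' `p = X't / t't`, `q = y't / t't`, then deflates both `X` and `y`.
#' Successive X-scores are mutually orthogonal. Component signs follow the
#' largest-|weight|-positive convention. If the requested number of latent
#' variables exceeds the effective rank the model is truncated with a
#' warning.
#'
#' @param x a [VocExperiment-class] or complete samples x features matrix.
#' @param labels class labels (ignored for a VocExperiment).
#' @param nLV number of latent variables (default 3).
#' @return A [PLSModel-class].
#' @export
setGeneric("fitPLSDA", function(x, labels = NULL, nLV = 3L)
  standardGeneric("fitPLSDA"))

#' @export
setMethod("fitPLSDA", "VocExperiment", function(x, labels = NULL, nLV = 3L)
  fitPLSDA(vocMatrix(x), classLabels(x), nLV))

#' @export
setMethod("fitPLSDA", "matrix", function(x, labels = NULL, nLV = 3L) {
  stopifnot(!anyNA(x), nLV >= 1)
  labels <- .asVocFactor(labels)
  stopifnot(length(labels) == nrow(x), nlevels(droplevels(labels)) == 2L)
  n <- nrow(x); p <- ncol(x)
  y0 <- as.numeric(labels == "CRC")
  yMean <- mean(y0)
  y <- y0 - yMean
  ssYTotal <- sum(y^2)
  center <- colMeans(x)
  X <- sweep(x, 2, center)
  ssXTotal <- sum(X^2)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- ssY <- ssX <- numeric(0)
  for (a in seq_len(nLV)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      warning("rank exhausted: truncated to ", a - 1L, " latent variable(s)")
      break
    }
    w <- w / nw
    t <- drop(X %*% w)
    tt <- sum(t^2)
    ## the deflated X is numerically empty along every y-covariant direction
    if (tt < 1e-12 * max(ssXTotal, 1e-300)) {
      warning("rank exhausted: truncated to ", a - 1L, " latent variable(s)")
      break
    }
    pl <- drop(crossprod(X, t)) / tt
    qa <- sum(y * t) / tt
    ## sign convention
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; t <- -t; pl <- -pl; qa <- -qa }
    X <- X - tcrossprod(t, pl)
    y <- y - qa * t
    W <- cbind(W, w); P <- cbind(P, pl); Tm <- cbind(Tm, t)
    q <- c(q, qa)
    ssY <- c(ssY, qa^2 * tt)
    ssX <- c(ssX, tt * sum(pl^2))
  }
  if (ncol(W) == 0L) stop("X carries no covariance with the class code")
  dimnames(W) <- dimnames(P) <- list(colnames(x),
                                     sprintf("LV%d", seq_len(ncol(W))))
  dimnames(Tm) <- list(rownames(x), colnames(W))
  new("PLSModel", center = center, yMean = yMean, weights = W,
      xLoadings = P, yLoadings = q, scores = Tm, ssY = ssY,
      xVarRatio = ssX / ssXTotal, yVarRatio = ssY / ssYTotal)
})

#' Project new data onto PLS latent variables
#'
#' Applies the fitted weights with the same deflation sequence used in
#' training; no labels are needed.
#'
#' @param model a [PLSModel-class].
#' @param x new data (matrix or [VocExperiment-class]).
#' @return samples x latent-variables score matrix.
#' @export
plsProject <- function(model, x) {
  stopifnot(is(model, "PLSModel"))
  if (is(x, "VocExperiment")) x <- vocMatrix(x)
  stopifnot(ncol(x) == nrow(model@weights))
  X <- sweep(x, 2, model@center)
  nLV <- ncol(model@weights)
  Tm <- matrix(0, nrow(X), nLV,
               dimnames = list(rownames(x), colnames(model@weights)))
  for (a in seq_len(nLV)) {
    t <- drop(X %*% model@weights[, a])
    X <- X - tcrossprod(t, model@xLoadings[, a])
    Tm[, a] <- t
  }
  Tm
}

#' Predicted class code from a PLS-DA model
#'
#' Fitted value of the centered 0/1 class code plus its mean; 0.5 is the
#' natural decision threshold.
#'
#' @param model a [PLSModel-class].
#' @param x new data.
#' @return numeric vector of predicted class codes.
#' @export
plsPredict <- function(model, x) {
  drop(plsProject(model, x) %*% model@yLoadings) + model@yMean
}

#' Variable importance in projection (VIP) scores
#'
#' `vip_j = sqrt( p * sum_a SS_a w_ja^2 / sum_a SS_a )` with unit-norm weight
#' columns and `SS_a` the Y sum of squares explained by component `a`. The
#' squared scores average to 1 over the features the model was fitted on
#' (`sum(vip^2) = p`).
#'
#' @param model a [PLSModel-class].
#' @return named numeric vector, one score per feature.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' m <- fitPLSDA(x, rep(c("CO", "CRC"), 10), nLV = 2)
#' sum(vipScores(m)^2)  # equals ncol(x)
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "PLSModel"))
  ssTotal <- sum(model@ssY)
  if (ssTotal <= 0) stop("zero explained Y variance; VIP undefined")
  p <- nrow(model@weights)
  w2 <- model@weights^2  # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% model@ssY) / ssTotal)
  names(vip) <- rownames(model@weights)
  vip
}
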