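## ---------------------------------------------------------------------------
## Orthogonal signal correction (NIPALS-style iterative variant)
## ---------------------------------------------------------------------------

#' Orthogonal signal correction
#'
#' Removes from `x` the dominant variation that is orthogonal to the class
#' code (sensor drift, batch artifacts). Per component, starting from the
#' first principal-component score, the score is orthogonalized against the
#' centered 0/1 class code, a weight vector is obtained by regressing `X` on
#' the score (inner PLS step), and the score is recomputed until it changes
#' by less than `tol`; the converged score/loading product is subtracted
#' from `X`. Each removed score is exactly orthogonal to the class code
#' (|correlation| < 1e-6 by construction). The stored weights transform
#' held-out data without using its labels via [oscApply()].
#'
#' If the data carry (numerically) no class-orthogonal structure the
#' component is skipped and `x` is returned unchanged.
#'
#' @param x a [VocExperiment-class] or complete samples x features matrix.
#' @param labels class labels (ignored for a VocExperiment).
#' @param nOsc number of OSC components to remove (default 1; 0 is the
#'   identity).
#' @param tol relative convergence tolerance on the score (default 1e-6).
#' @param maxIter iteration cap (default 2000).
#' @return list with `corrected` (same type as `x`) and `model`
#'   ([OSCModel-class]).
#' @export
setGeneric("oscCorrect", function(x, labels = NULL, nOsc = 1L, tol = 1e-6,
                                  maxIter = 2000L)
  standardGeneric("oscCorrect"))

#' @export
setMethod("oscCorrect", "VocExperiment",
          function(x, labels = NULL, nOsc = 1L, tol = 1e-6, maxIter = 2000L) {
  res <- oscCorrect(vocMatrix(x), classLabels(x), nOsc, tol, maxIter)
  res$corrected <- setVocMatrix(x, res$corrected)
  res
})

#' @export
setMethod("oscCorrect", "matrix",
          function(x, labels = NULL, nOsc = 1L, tol = 1e-6, maxIter = 2000L) {
  stopifnot(!anyNA(x), nOsc >= 0)
  labels <- .asVocFactor(labels)
  stopifnot(length(labels) == nrow(x))
  if (nOsc == 0)  # identity: nothing removed, input returned bit-for-bit
    return(list(corrected = x,
                model = new("OSCModel", center = colMeans(x),
                            weights = matrix(0, ncol(x), 0),
                            loadings = matrix(0, ncol(x), 0),
                            scores = matrix(0, nrow(x), 0),
                            scoreYCor = numeric(0),
                            variant = "NIPALS-OSC (orthogonalized score, inner PLS weight)")))
  center <- colMeans(x)
  X <- sweep(x, 2, center)
  y <- as.numeric(labels == "CRC")
  y <- y - mean(y)
  yy <- sum(y^2)
  p <- ncol(x)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(x), 0)
  cors <- numeric(0)
  scale0 <- sqrt(sum(X^2))
  for (a in seq_len(nOsc)) {
    if (sum(X^2) < (1e-12 * max(scale0, 1))^2) break
    sv <- svd(X, nu = 1L, nv = 0L)
    t <- sv$u[, 1] * sv$d[1]  # first principal-component score of X
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      tOrth <- t - y * sum(y * t) / yy
      nOrth <- sqrt(sum(tOrth^2))
      if (nOrth < 1e-10 * max(sqrt(sum(t^2)), 1e-30)) {
        ## no class-orthogonal structure left: skip this component
        t <- NULL
        converged <- TRUE
        break
      }
      w <- drop(crossprod(X, tOrth)) / sum(tOrth^2)
      w <- w / sqrt(sum(w^2))
      tNew <- drop(X %*% w)
      delta <- sqrt(sum((tNew - t)^2)) / sqrt(sum(tNew^2))
      t <- tNew
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("OSC did not converge in %d iterations (last delta %.3g)",
                   maxIter, delta))
    if (is.null(t)) break
    ## final orthogonalization so the removed score is exactly y-orthogonal
    t <- t - y * sum(y * t) / yy
    tt <- sum(t^2)
    if (tt < 1e-20) break
    pl <- drop(crossprod(X, t)) / tt
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; t <- -t; pl <- -pl }
    X <- X - tcrossprod(t, pl)
    W <- cbind(W, w); P <- cbind(P, pl); Tm <- cbind(Tm, t)
    cors <- c(cors, abs(sum(y * t)) / sqrt(yy * tt))
  }
  if (ncol(W) > 0) {
    dimnames(W) <- dimnames(P) <- list(colnames(x),
                                       sprintf("OSC%d", seq_len(ncol(W))))
    dimnames(Tm) <- list(rownames(x), colnames(W))
  }
  corrected <- sweep(X, 2, center, "+")
  dimnames(corrected) <- dimnames(x)
  list(corrected = corrected,
       model = new("OSCModel", center = center, weights = W, loadings = P,
                   scores = Tm, scoreYCor = cors,
                   variant = "NIPALS-OSC (orthogonalized score, inner PLS weight)"))
})

#' Apply a fitted OSC correction to new data
#'
#' Uses the stored weights and loadings only; the labels of `x` (if any)
#' are not consulted.
#'
#' @param model an [OSCModel-class].
#' @param x new data (matrix or [VocExperiment-class]).
#' @return corrected data, same type and shape as `x`.
#' @export
oscApply <- function(model, x) {
  stopifnot(is(model, "OSCModel"))
  if (is(x, "VocExperiment"))
    return(setVocMatrix(x, oscApply(model, vocMatrix(x))))
  stopifnot(ncol(x) == length(model@center))
  X <- sweep(x, 2, model@center)
  for (a in seq_len(ncol(model@weights))) {
    t <- drop(X %*% model@weights[, a])
    X <- X - tcrossprod(t, model@loadings[, a])
  }
  out <- sweep(X, 2, model@center, "+")
  dimnames(out) <- dimnames(x)
  out
}
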