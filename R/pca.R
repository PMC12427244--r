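## ---------------------------------------------------------------------------
## PCA by singular value decomposition of the column-centered data
## ---------------------------------------------------------------------------

## deterministic sign convention: the largest-|value| element of each column
## of `basis` is made positive; `scores` columns flip accordingly
.fixSigns <- function(basis, scores = NULL) {
  for (a in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, a]))
    if (basis[i, a] < 0) {
      basis[, a] <- -basis[, a]
      if (!is.null(scores)) scores[, a] <- -scores[, a]
    }
  }
  if (is.null(scores)) basis else list(basis = basis, scores = scores)
}

#' Fit a principal component analysis
#'
#' SVD of the column-centered data. Explained-variance ratios are squared
#' singular values over the total centered sum of squares, so they sum to 1
#' over all `min(n - 1, p)` components. Component signs follow a fixed
#' convention (largest-magnitude loading positive) so scores are reproducible
#' bit-for-bit.
#'
#' @param x a [VocExperiment-class] or complete samples x features matrix.
#' @param nComponents number of components to keep
#'   (`<= min(n - 1, p)`).
#' @return A [PCAModel-class].
#' @examples
#' m <- fitPCA(cbind(1:10, (1:10) * 2 + rnorm(10, 0, 1e-3)), 2)
#' m@varRatio
#' @export
setGeneric("fitPCA", function(x, nComponents = 3L) standardGeneric("fitPCA"))

#' @export
setMethod("fitPCA", "VocExperiment", function(x, nComponents = 3L)
  fitPCA(vocMatrix(x), nComponents))

#' @export
setMethod("fitPCA", "matrix", function(x, nComponents = 3L) {
  stopifnot(!anyNA(x))
  n <- nrow(x); p <- ncol(x)
  stopifnot(nComponents >= 1, nComponents <= min(n - 1, p))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  totalSS <- sum(xc^2)
  if (totalSS < 1e-12) stop("constant matrix: no variance to decompose")
  sv <- svd(xc, nu = nComponents, nv = nComponents)
  fixed <- .fixSigns(sv$v,
                     sv$u %*% diag(sv$d[seq_len(nComponents)],
                                   nComponents, nComponents))
  loadings <- fixed$basis
  scores <- fixed$scores
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores) <- sprintf("PC%d", seq_len(nComponents))
  rownames(scores) <- rownames(x)
  new("PCAModel", center = center, loadings = loadings, scores = scores,
      varRatio = sv$d[seq_len(nComponents)]^2 / totalSS)
})

#' Project data onto fitted principal components
#'
#' @param model a [PCAModel-class].
#' @param x new data (matrix or [VocExperiment-class]) with the same
#'   features as the training data.
#' @return samples x components score matrix.
#' @export
projectPCA <- function(model, x) {
  stopifnot(is(model, "PCAModel"))
  if (is(x, "VocExperiment")) x <- vocMatrix(x)
  stopifnot(ncol(x) == nrow(model@loadings))
  sweep(x, 2, model@center) %*% model@loadings
}
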