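## ---------------------------------------------------------------------------
## Missing-value imputation and the normalization suite
## ---------------------------------------------------------------------------

#' Moving-average imputation of missing peaks
#'
#' Each missing entry is replaced by the mean of the observed values inside a
#' centered window of `window` rows of the same column (rows in stored order,
#' matching time-ordered acquisition; the window truncates at the matrix
#' edges). If every value in the window is missing, the column mean of the
#' observed values is used. Observed values are never altered, and all
#' replacements are computed from the original observed entries, so the
#' operation is order-independent and idempotent.
#'
#' @param x a [VocExperiment-class] or numeric matrix (samples x features).
#' @param window odd window size >= 3 (default 3).
#' @return same type as `x`, with no missing entries.
#' @examples
#' imputeMovingAverage(matrix(c(1, NA, 3), 3, 1))
#' @export
imputeMovingAverage <- function(x, window = 3L) {
  if (is(x, "VocExperiment"))
    return(setVocMatrix(x, imputeMovingAverage(vocMatrix(x), window)))
  stopifnot(is.matrix(x), window >= 3, window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  n <- nrow(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    miss <- which(is.na(x[, j]))
    if (length(miss) == 0L) next
    obs <- x[, j]
    if (all(is.na(obs)))
      stop("column ", colnames(x)[j] %||% j,
           " is fully missing; drop it upstream")
    colMean <- mean(obs, na.rm = TRUE)
    for (i in miss) {
      w <- obs[max(1L, i - half):min(n, i + half)]
      w <- w[!is.na(w)]
      out[i, j] <- if (length(w)) mean(w) else colMean
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normMethods <- c("minmax", "zscore", "quantile", "pareto", "autoscale",
                  "log", "sqrt")

#' Fit a normalization on training data
#'
#' Learns per-feature parameters on `x` (the training set) and returns a
#' `NormalizationSpec` that can be applied to held-out data without touching
#' its statistics. Methods:
#' \describe{
#'   \item{minmax}{scale each feature to `[0, 1]` by its training min/max.}
#'   \item{zscore, autoscale}{mean-center and scale to unit variance
#'     (population sd, one consistent convention); the two names are
#'     synonyms.}
#'   \item{pareto}{mean-center and divide by the square root of the sd.}
#'   \item{quantile}{force every feature to the training per-rank mean
#'     distribution (rank averaging with midrank ties).}
#'   \item{log}{natural log of `x + offset`; `offset = 1` is applied only
#'     when zeros are present.}
#'   \item{sqrt}{element-wise square root of non-negative values.}
#' }
#' Standard deviations are floored at 1e-12 so constant features map to zero
#' rather than dividing by zero.
#'
#' @param x training data, [VocExperiment-class] or samples x features
#'   matrix, complete (impute first).
#' @param method one of `"minmax"`, `"zscore"`, `"quantile"`, `"pareto"`,
#'   `"autoscale"`, `"log"`, `"sqrt"`.
#' @return a `NormalizationSpec` (list with the learned parameters).
#' @examples
#' spec <- fitNormalizer(matrix(c(0, 5, 10), 3, 1), "minmax")
#' applyNormalizer(spec, matrix(c(0, 5, 10), 3, 1))
#' @export
fitNormalizer <- function(x, method = c("autoscale", "minmax", "zscore",
                                        "quantile", "pareto", "log", "sqrt")) {
  if (is(x, "VocExperiment")) x <- vocMatrix(x)
  method <- match.arg(method)
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("normalization requires a complete matrix; impute first")
  eps <- 1e-12
  popSd <- function(v) sqrt(mean((v - mean(v))^2))
  params <- switch(method,
    minmax = list(min = apply(x, 2, min),
                  range = pmax(apply(x, 2, max) - apply(x, 2, min), eps)),
    zscore = ,
    autoscale = list(mean = colMeans(x),
                     sd = pmax(apply(x, 2, popSd), eps)),
    pareto = list(mean = colMeans(x),
                  sqrtSd = pmax(sqrt(apply(x, 2, popSd)), eps)),
    quantile = list(reference = rowMeans(apply(x, 2, sort))),
    log = {
      if (any(x < 0)) stop("log transform requires non-negative values")
      list(offset = if (any(x == 0)) 1 else 0)
    },
    sqrt = {
      if (any(x < 0)) stop("sqrt transform requires non-negative values")
      list()
    })
  structure(list(method = method, params = params, nFeatures = ncol(x),
                 featureNames = colnames(x)),
            class = "NormalizationSpec")
}

#' @rdname fitNormalizer
#' @param spec a `NormalizationSpec` from `fitNormalizer`.
#' @export
applyNormalizer <- function(spec, x) {
  stopifnot(inherits(spec, "NormalizationSpec"))
  if (is(x, "VocExperiment"))
    return(setVocMatrix(x, applyNormalizer(spec, vocMatrix(x))))
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("normalization requires a complete matrix; impute first")
  if (spec$method %in% c("minmax", "zscore", "autoscale", "pareto", "quantile")
      && ncol(x) != spec$nFeatures)
    stop("feature count differs from the fitted spec")
  p <- spec$params
  out <- switch(spec$method,
    minmax = sweep(sweep(x, 2, p$min), 2, p$range, "/"),
    zscore = ,
    autoscale = sweep(sweep(x, 2, p$mean), 2, p$sd, "/"),
    pareto = sweep(sweep(x, 2, p$mean), 2, p$sqrtSd, "/"),
    quantile = {
      ref <- p$reference
      nRef <- length(ref)
      apply(x, 2, function(v) {
        pr <- (rank(v, ties.method = "average") - 0.5) / length(v)
        approx(x = (seq_len(nRef) - 0.5) / nRef, y = ref, xout = pr,
               rule = 2)$y
      })
    },
    log = {
      if (any(x + p$offset <= 0))
        stop("log transform: non-positive values after offset")
      log(x + p$offset)
    },
    sqrt = {
      if (any(x < 0)) stop("sqrt transform requires non-negative values")
      sqrt(x)
    })
  dimnames(out) <- dimnames(x)
  out
}

#' @export
print.NormalizationSpec <- function(x, ...) {
  cat(sprintf("NormalizationSpec: %s over %d feature(s)\n",
              x$method, x$nFeatures))
  invisible(x)
}

#' Serialize / read a NormalizationSpec sidecar file
#'
#' Plain-text key/value format so cross-validation folds and reports are
#' auditable.
#' @param spec a `NormalizationSpec`.
#' @param path file path.
#' @export
writeNormalizationSpec <- function(spec, path) {
  stopifnot(inherits(spec, "NormalizationSpec"))
  lines <- c(sprintf("method\t%s", spec$method),
             sprintf("nFeatures\t%d", spec$nFeatures),
             sprintf("featureNames\t%s",
                     paste(spec$featureNames %||% "", collapse = ",")),
             vapply(names(spec$params), function(nm) {
               sprintf("param:%s\t%s", nm,
                       paste(sprintf("%.17g", spec$params[[nm]]),
                             collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNormalizationSpec
#' @export
readNormalizationSpec <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  kv <- stats::setNames(lapply(lines, `[`, 2), vapply(lines, `[`, "", 1))
  params <- list()
  for (nm in names(kv)) {
    if (startsWith(nm, "param:"))
      params[[sub("^param:", "", nm)]] <-
        as.numeric(strsplit(kv[[nm]], ",")[[1]])
  }
  fn <- strsplit(kv$featureNames, ",")[[1]]
  structure(list(method = kv$method, params = params,
                 nFeatures = as.integer(kv$nFeatures),
                 featureNames = if (length(fn) && nzchar(fn[1])) fn else NULL),
            class = "NormalizationSpec")
}
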