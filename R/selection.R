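## ---------------------------------------------------------------------------
## Univariate Wilcoxon rank-sum screening with variance fallback
## ---------------------------------------------------------------------------

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` of `x` within the pooled sample (midranks for
#' ties). The two-sided p-value is exact (full enumeration of rank
#' assignments) when `length(x) + length(y) <= 12` and there are no ties,
#' and otherwise uses the normal approximation with tie-corrected variance
#' and continuity correction; `mode` can force either branch.
#'
#' @param x,y numeric samples from the two groups (each non-empty).
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return list with `W` (rank sum of `x`), `p` (two-sided), `degenerate`
#'   (`TRUE` when all pooled values are identical, in which case `p = 1`).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1,
            !anyNA(x), !anyNA(y))
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  W <- sum(r[seq_len(nx)])
  ties <- table(pooled)
  hasTies <- any(ties > 1)
  if (length(ties) == 1L)  # all values identical: no information
    return(list(W = W, p = 1, degenerate = TRUE))
  if (mode == "auto")
    mode <- if (n <= 12 && !hasTies) "exact" else "normal"
  mu <- nx * (n + 1) / 2
  if (mode == "exact") {
    if (hasTies)
      stop("exact mode requires tie-free data; use mode = 'normal'")
    sums <- combn(r, nx, sum)
    p <- sum(abs(sums - mu) >= abs(W - mu) - 1e-9) / length(sums)
  } else {
    tieAdj <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tieAdj)
    if (sigma2 <= 0)
      return(list(W = W, p = 1, degenerate = TRUE))
    d <- W - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(W = W, p = p, degenerate = FALSE)
}

#' Univariate feature screening
#'
#' Applies [wilcoxonRankSum()] to every feature and selects those with
#' `p < alpha` (no multiple-testing correction by default, mirroring raw
#' p-value screening; set `adjust = "BH"` for Benjamini-Hochberg). If no
#' feature reaches the threshold, the `kFallback` features with the highest
#' variance are selected instead. Because variances are all ~1 after
#' autoscaling, the fallback ranking can (and should) be computed on the
#' pre-scaling matrix supplied as `varianceSource`.
#'
#' @param x a [VocExperiment-class] or samples x features matrix, complete.
#' @param labels class labels (taken from `x` when it is a VocExperiment).
#' @param alpha significance threshold (default 0.05).
#' @param kFallback number of highest-variance features selected when
#'   nothing is significant (default 13); capped at the feature count with a
#'   warning.
#' @param varianceSource optional matrix (same columns as `x`) on which the
#'   fallback variance ranking is computed; defaults to `x` itself.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list of class `SelectionResult`: `table` (per-feature data.frame
#'   with `feature`, `W`, `p`, `meanCO`, `meanCRC`, `direction`,
#'   `selected`), `selected` (feature names, input order), `fallbackUsed`,
#'   `alpha`, `kFallback`.
#' @export
selectFeatures <- function(x, labels = NULL, alpha = 0.05, kFallback = 13L,
                           varianceSource = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is(x, "VocExperiment")) {
    labels <- classLabels(x)
    x <- vocMatrix(x)
  }
  stopifnot(is.matrix(x), !anyNA(x))
  labels <- .asVocFactor(labels)
  stopifnot(length(labels) == nrow(x))
  isCrc <- labels == "CRC"
  res <- apply(x, 2, function(v)
    unlist(wilcoxonRankSum(v[!isCrc], v[isCrc], mode = "auto")[c("W", "p")]))
  p <- res["p", ]
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  meanCO <- colMeans(x[!isCrc, , drop = FALSE])
  meanCRC <- colMeans(x[isCrc, , drop = FALSE])
  feats <- colnames(x) %||% as.character(seq_len(ncol(x)))
  selected <- p < alpha
  fallbackUsed <- FALSE
  if (!any(selected)) {
    fallbackUsed <- TRUE
    if (kFallback > ncol(x)) {
      warning("kFallback exceeds feature count; capped")
      kFallback <- ncol(x)
    }
    vsrc <- varianceSource %||% x
    stopifnot(ncol(vsrc) == ncol(x))
    vars <- apply(vsrc, 2, var)
    selected <- seq_len(ncol(x)) %in%
      order(vars, decreasing = TRUE)[seq_len(kFallback)]
  }
  tab <- data.frame(feature = feats, W = res["W", ], p = p,
                    meanCO = meanCO, meanCRC = meanCRC,
                    direction = ifelse(meanCRC > meanCO, "CRC", "CO"),
                    selected = selected, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, selected = feats[selected],
                 fallbackUsed = fallbackUsed, alpha = alpha,
                 kFallback = as.integer(kFallback)),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("SelectionResult: %d of %d features selected%s (alpha = %g)\n",
              length(x$selected), nrow(x$table),
              if (x$fallbackUsed) " by variance fallback" else "", x$alpha))
  invisible(x)
}

#' Write a selection result as CSV
#'
#' Columns: feature, statistic, p_value, mean_CO, mean_CRC, direction,
#' selected.
#' @param sel a `SelectionResult`.
#' @param path CSV path.
#' @export
writeSelectionResult <- function(sel, path) {
  stopifnot(inherits(sel, "SelectionResult"))
  tab <- sel$table
  write.csv(data.frame(feature = tab$feature, statistic = tab$W,
                       p_value = tab$p, mean_CO = tab$meanCO,
                       mean_CRC = tab$meanCRC, direction = tab$direction,
                       selected = tab$selected),
            path, row.names = FALSE)
  invisible(path)
}
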