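## ---------------------------------------------------------------------------
## Confusion matrices, metric panels, ROC/AUC
## ---------------------------------------------------------------------------

#' Confusion counts for a binary CO/CRC classification
#'
#' CO is the negative class and CRC the positive class, so `tn` counts
#' correctly classified CO samples and `tp` correctly classified CRC
#' samples.
#'
#' @param truth,pred label vectors of equal length (values CO/CRC).
#' @return 2x2 integer matrix with rows = truth, columns = predicted.
#' @examples
#' confusionCounts(c("CO", "CO", "CRC"), c("CO", "CRC", "CRC"))
#' @export
confusionCounts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- .asVocFactor(truth)
  pred <- .asVocFactor(pred)
  tab <- table(truth = truth, predicted = pred)
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}

#' Build a confusion matrix directly from its four counts
#'
#' Convenience for reproducing metric panels from published counts.
#' @param tn,fp,fn,tp counts with CO negative and CRC positive: `tn` CO
#'   predicted CO, `fp` CO predicted CRC, `fn` CRC predicted CO, `tp` CRC
#'   predicted CRC.
#' @return 2x2 matrix as from [confusionCounts()].
#' @export
confusionFromCounts <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  matrix(c(tn, fn, fp, tp), 2, 2,
         dimnames = list(truth = .vocClasses, predicted = .vocClasses))
}

#' Classification metric panel
#'
#' Overall accuracy plus per-class accuracy-rate, sensitivity, specificity,
#' precision and F1, each class in turn treated as positive (role
#' reversal). All values are percentages at full precision; round only at
#' the reporting layer ([formatMetrics()]). The per-class `rate` is the
#' fraction of that class's samples classified correctly; `fp_rate` /
#' `fn_rate` are the complements for CO and CRC respectively.
#'
#' @param confusion 2x2 matrix from [confusionCounts()] /
#'   [confusionFromCounts()].
#' @return data.frame with columns `metric`, `class`, `value` (percent).
#' @examples
#' metricsPanel(confusionFromCounts(tn = 30, fp = 4, fn = 8, tp = 23))
#' @export
metricsPanel <- function(confusion) {
  stopifnot(identical(dim(confusion), c(2L, 2L)), all(confusion >= 0))
  tn <- confusion["CO", "CO"]; fp <- confusion["CO", "CRC"]
  fn <- confusion["CRC", "CO"]; tp <- confusion["CRC", "CRC"]
  total <- tn + fp + fn + tp
  stopifnot(total > 0)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  ## per-class panel: first treating CRC as positive, then CO as positive
  sensCRC <- pct(tp, tp + fn); specCRC <- pct(tn, tn + fp)
  precCRC <- pct(tp, tp + fp)
  f1CRC <- if (is.na(sensCRC) || is.na(precCRC) || sensCRC + precCRC == 0)
    NA_real_ else 2 * precCRC * sensCRC / (precCRC + sensCRC)
  sensCO <- pct(tn, tn + fp); specCO <- pct(tp, tp + fn)
  precCO <- pct(tn, tn + fn)
  f1CO <- if (is.na(sensCO) || is.na(precCO) || sensCO + precCO == 0)
    NA_real_ else 2 * precCO * sensCO / (precCO + sensCO)
  data.frame(
    metric = c("accuracy", "rate", "rate", "fp_rate", "fn_rate",
               "sensitivity", "sensitivity", "specificity", "specificity",
               "precision", "precision", "f1", "f1"),
    class = c("overall", "CO", "CRC", "CO", "CRC",
              "CO", "CRC", "CO", "CRC", "CO", "CRC", "CO", "CRC"),
    value = c(pct(tn + tp, total), sensCO, sensCRC,
              pct(fp, tn + fp), pct(fn, tp + fn),
              sensCO, sensCRC, specCO, specCRC,
              precCO, precCRC, f1CO, f1CRC),
    stringsAsFactors = FALSE)
}

#' Report-layer rounding of a metric panel
#'
#' @param panel data.frame from [metricsPanel()].
#' @param digits decimal places (default 1, matching standard reporting).
#' @return the panel with `value` rounded.
#' @export
formatMetrics <- function(panel, digits = 1L) {
  panel$value <- round(panel$value, digits)
  panel
}

## panel lookup helper used in pipelines and tests
metricValue <- function(panel, metric, class = "overall") {
  v <- panel$value[panel$metric == metric & panel$class == class]
  stopifnot(length(v) == 1L)
  v
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (descending); each threshold
#' classifies scores `>= threshold` as CRC, yielding one (FPR, TPR) point.
#' The AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney U statistic with half-credit for tied scores.
#'
#' @param truth label vector (both classes must be present).
#' @param scores numeric scores, higher = more CRC-like.
#' @return list of class `rocResult`: `points` (data.frame `threshold`,
#'   `fpr`, `tpr`, including the (0,0) and (1,1) endpoints) and `auc`.
#' @examples
#' rocAuc(c("CO", "CO", "CRC", "CRC"), c(0.1, 0.4, 0.35, 0.8))$auc
#' @export
rocAuc <- function(truth, scores) {
  truth <- .asVocFactor(truth)
  stopifnot(length(truth) == length(scores), !anyNA(scores))
  nPos <- sum(truth == "CRC"); nNeg <- sum(truth == "CO")
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == "CRC") / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == "CO") / nNeg,
                numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "rocResult")
}

#' @importFrom utils head tail
#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}
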