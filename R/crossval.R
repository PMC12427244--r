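## ---------------------------------------------------------------------------
## Stratified cross-validation engine with pluggable transform pipeline
## ---------------------------------------------------------------------------

#' Cross-validate a classifier with an optional transform pipeline
#'
#' Runs stratified k-fold cross-validation and pools the out-of-fold
#' predictions into a single confusion matrix, metric panel and ROC curve
#' (pooling whole-cohort counts rather than averaging per-fold metrics).
#'
#' The transform pipeline (normalization, feature selection, OSC, PCA or
#' PLS-DA projection, ...) is supplied as a pair of functions:
#' `fitTransform(trainX, trainY)` returning an arbitrary fitted object, and
#' `applyTransform(fit, x)` mapping held-out data into the transformed
#' space. A label-aware transform (e.g. OSC, whose removed training scores
#' are orthogonalized against the labels) may include the transformed
#' training data as element `train` of the fitted object; it is then used
#' for the data the transform was fitted on instead of `applyTransform`.
#' Two leakage policies are supported:
#' \describe{
#'   \item{honest}{the default: the transform is refitted inside every
#'     training fold and applied to the held-out fold, so no information
#'     from held-out samples reaches the model.}
#'   \item{as_paper}{the transform is fitted once on the full data before
#'     cross-validation, as chemometric studies commonly do; only the
#'     classifier is cross-validated. This overstates performance and is
#'     provided to reproduce that practice; results always record the
#'     mode.}
#' }
#'
#' @param x samples x features matrix or [VocExperiment-class].
#' @param labels class labels (ignored for a VocExperiment).
#' @param classifier `"knn"`, `"lda"`, `"lr"` or `"svm"`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @param mode `"honest"` or `"as_paper"`.
#' @param fitTransform,applyTransform optional transform pipeline (both or
#'   neither).
#' @param classifierArgs list of extra arguments for the classifier (e.g.
#'   `list(k = 5)`).
#' @return A [CVResult-class].
#' @examples
#' x <- rbind(matrix(rnorm(100), 20), matrix(rnorm(100, 2), 20))
#' cv <- crossValidate(x, rep(c("CO", "CRC"), each = 20), "lda", seed = 1)
#' cv@auc
#' @export
crossValidate <- function(x, labels = NULL, classifier = c("knn", "lda", "lr", "svm"),
                          folds = 5L, seed = 1L,
                          mode = c("honest", "as_paper"),
                          fitTransform = NULL, applyTransform = NULL,
                          classifierArgs = list()) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  if (is(x, "VocExperiment")) {
    labels <- classLabels(x)
    x <- vocMatrix(x)
  }
  labels <- .asVocFactor(labels)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (xor(is.null(fitTransform), is.null(applyTransform)))
    stop("supply both fitTransform and applyTransform, or neither")
  clf <- .classifierFuns(classifier, classifierArgs)
  foldId <- stratifiedKFold(labels, folds, seed = seed)
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = .vocClasses)
  score <- rep(NA_real_, n)
  if (mode == "as_paper" && !is.null(fitTransform)) {
    fitAll <- fitTransform(x, labels)
    z <- fitAll$train %||% applyTransform(fitAll, x)
    for (f in seq_len(folds)) {
      te <- foldId == f
      out <- clf(z[!te, , drop = FALSE], labels[!te], z[te, , drop = FALSE])
      pred[te] <- out$pred
      score[te] <- out$score
    }
  } else {
    for (f in seq_len(folds)) {
      te <- foldId == f
      trX <- x[!te, , drop = FALSE]
      teX <- x[te, , drop = FALSE]
      if (!is.null(fitTransform)) {
        fit <- fitTransform(trX, labels[!te])
        teX <- applyTransform(fit, teX)
        trX <- fit$train %||% applyTransform(fit, trX)
      }
      out <- clf(trX, labels[!te], teX)
      pred[te] <- out$pred
      score[te] <- out$score
    }
  }
  stopifnot(!anyNA(pred), !anyNA(score))
  conf <- confusionCounts(labels, pred)
  roc <- rocAuc(labels, score)
  new("CVResult", folds = as.integer(foldId), truth = labels,
      predicted = pred, scores = score, confusion = conf,
      metrics = metricsPanel(conf), roc = roc$points, auc = roc$auc,
      classifier = classifier, mode = mode, seed = as.integer(seed))
}

#' Overall cross-validated accuracy of a CVResult (percent)
#'
#' @param result a [CVResult-class].
#' @return numeric scalar, percent scale.
#' @export
cvAccuracy <- function(result) {
  stopifnot(is(result, "CVResult"))
  metricValue(result@metrics, "accuracy", "overall")
}

#' Write the report files of a CVResult
#'
#' Emits `confusion.csv`, `metrics.csv` (1-decimal percentages),
#' `roc.csv` and `predictions.csv` under `dir`.
#'
#' @param result a [CVResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCVResult <- function(result, dir) {
  stopifnot(is(result, "CVResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(result@confusion),
            file.path(dir, "confusion.csv"), row.names = FALSE)
  write.csv(formatMetrics(result@metrics),
            file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(result@roc, file.path(dir, "roc.csv"), row.names = FALSE)
  write.csv(data.frame(sample = names(result@truth) %||%
                         seq_along(result@truth),
                       fold = result@folds,
                       truth = as.character(result@truth),
                       predicted = as.character(result@predicted),
                       score = result@scores),
            file.path(dir, "predictions.csv"), row.names = FALSE)
  invisible(dir)
}
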