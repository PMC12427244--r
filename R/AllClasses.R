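#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx cor median pnorm quantile rnorm runif sd var
#' @importFrom utils combn read.csv write.csv
NULL

## Class labels used throughout: CO (control, negative) and CRC (case,
## positive). All label vectors are coerced to this factor.
.vocClasses <- c("CO", "CRC")

.asVocFactor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .vocClasses)
  if (length(bad) > 0L)
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected CO or CRC)")
  factor(labels, levels = .vocClasses)
}

#' VocExperiment: samples-by-features volatilome container
#'
#' `VocExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds one assay (`"area"`) of feature values (GC-MS peak areas or E-nose
#' Max-Min amplitudes) with a mandatory two-level class label (`CO`/`CRC`) in
#' `colData(x)$class`. Following Bioconductor convention features are rows and
#' samples are columns internally; [vocMatrix()] returns the chemometric
#' samples x features orientation.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("VocExperiment", contains = "SummarizedExperiment")

setValidity("VocExperiment", function(object) {
  msgs <- character()
  if (!"area" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'area' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"class" %in% colnames(cd)) {
    msgs <- c(msgs, "colData column 'class' is required")
  } else {
    cls <- cd$class
    if (!is.factor(cls) || !identical(levels(cls), .vocClasses))
      msgs <- c(msgs, "colData$class must be a factor with levels CO, CRC")
    if (anyNA(cls))
      msgs <- c(msgs, "class labels must not be NA")
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate feature names")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VocExperiment
#'
#' @param values numeric matrix, samples in rows and features in columns
#'   (the orientation chemometric software works in). May contain `NA` for
#'   missing peaks.
#' @param labels class labels, one per sample, each `"CO"` or `"CRC"`.
#' @param sampleIds optional sample identifiers; default row names of
#'   `values` or `S001`, `S002`, ...
#' @param featureNames optional feature names; default column names of
#'   `values` or `F001`, ...
#' @return A [VocExperiment-class] object.
#' @examples
#' ve <- VocExperiment(matrix(rnorm(12), 4, 3), c("CO", "CO", "CRC", "CRC"))
#' dim(ve)
#' @export
VocExperiment <- function(values, labels, sampleIds = NULL,
                          featureNames = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(labels) != nrow(values))
    stop("length(labels) must equal nrow(values)")
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else sprintf("S%03d", seq_len(nrow(values)))
  if (anyDuplicated(sampleIds)) stop("duplicate sample ids")
  if (is.null(featureNames))
    featureNames <- if (!is.null(colnames(values))) colnames(values)
                    else sprintf("F%03d", seq_len(ncol(values)))
  a <- t(values)
  dimnames(a) <- list(featureNames, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(area = a),
    colData = S4Vectors::DataFrame(class = .asVocFactor(labels),
                                   row.names = sampleIds))
  new("VocExperiment", se)
}

#' PeakTable: one sample's GC-MS peak list
#'
#' Retention-time / integrated-area pairs for a single chromatographic run,
#' optionally with the internal-standard (limonene) peak area.
#'
#' @slot sampleId single sample identifier.
#' @slot peaks data.frame with numeric columns `rt` (minutes) and
#'   `area` (>= 0).
#' @slot isArea internal-standard peak area (`NA` when not recorded).
#' @export
setClass("PeakTable",
         representation(sampleId = "character", peaks = "data.frame",
                        isArea = "numeric"))

setValidity("PeakTable", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be scalar")
  pk <- object@peaks
  if (!all(c("rt", "area") %in% colnames(pk)))
    msgs <- c(msgs, "peaks needs columns rt and area")
  else {
    if (any(pk$rt <= 0)) msgs <- c(msgs, "retention times must be positive")
    if (any(pk$area < 0)) msgs <- c(msgs, "peak areas must be non-negative")
  }
  if (length(object@isArea) != 1L) msgs <- c(msgs, "isArea must be scalar")
  else if (!is.na(object@isArea) && object@isArea <= 0)
    msgs <- c(msgs, "internal-standard area must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeakTable
#'
#' @param sampleId sample identifier.
#' @param rt numeric retention times in minutes.
#' @param area numeric peak areas (same length as `rt`).
#' @param isArea optional internal-standard (limonene) peak area.
#' @return A [PeakTable-class] object.
#' @export
peakTable <- function(sampleId, rt, area, isArea = NA_real_) {
  new("PeakTable", sampleId = as.character(sampleId),
      peaks = data.frame(rt = as.numeric(rt), area = as.numeric(area)),
      isArea = as.numeric(isArea))
}

#' SensorRecording: one E-nose acquisition
#'
#' A timestamped multichannel transient from the 14-sensor array, with each
#' timestamp tagged by acquisition phase (`stabilize`, `baseline`, `sample`,
#' `purge`).
#'
#' @slot sampleId sample identifier.
#' @slot label class label (`CO`/`CRC`), `NA` allowed for unlabeled runs.
#' @slot time numeric seconds, strictly increasing.
#' @slot phase character phase tag per timestamp.
#' @slot channels numeric matrix, timestamps x sensors, with sensor labels
#'   as column names.
#' @export
setClass("SensorRecording",
         representation(sampleId = "character", label = "character",
                        time = "numeric", phase = "character",
                        channels = "matrix"))

.vocPhases <- c("stabilize", "baseline", "sample", "purge")

setValidity("SensorRecording", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (n > 1 && any(diff(object@time) <= 0))
    msgs <- c(msgs, "time must be strictly increasing")
  if (length(object@phase) != n)
    msgs <- c(msgs, "phase must match time length")
  if (!all(object@phase %in% .vocPhases))
    msgs <- c(msgs, "unknown phase tag")
  if (nrow(object@channels) != n)
    msgs <- c(msgs, "channels must have one row per timestamp")
  if (is.null(colnames(object@channels)))
    msgs <- c(msgs, "channels must have sensor names")
  if (!is.na(object@label) && !object@label %in% .vocClasses)
    msgs <- c(msgs, "label must be CO, CRC or NA")
  ## phases must appear as contiguous blocks in acquisition order
  ph <- rle(object@phase)$values
  if (anyDuplicated(ph) || !all(match(ph, .vocPhases) == sort(match(ph, .vocPhases))))
    msgs <- c(msgs, "phases must be contiguous and in acquisition order")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SensorRecording
#'
#' @param sampleId sample identifier.
#' @param time numeric seconds, strictly increasing.
#' @param channels matrix timestamps x sensors with sensor names as columns.
#' @param phase phase tag per timestamp; defaults to all `"sample"`.
#' @param label optional class label.
#' @return A [SensorRecording-class] object.
#' @export
sensorRecording <- function(sampleId, time, channels,
                            phase = rep("sample", length(time)),
                            label = NA_character_) {
  new("SensorRecording", sampleId = as.character(sampleId),
      label = as.character(label), time = as.numeric(time),
      phase = as.character(phase), channels = as.matrix(channels))
}

#' PCAModel: principal component decomposition
#'
#' @slot center feature means used for centering.
#' @slot loadings features x components orthonormal loading matrix.
#' @slot scores samples x components score matrix.
#' @slot varRatio fraction of total centered variance per component.
#' @export
setClass("PCAModel",
         representation(center = "numeric", loadings = "matrix",
                        scores = "matrix", varRatio = "numeric"))

#' PLSModel: NIPALS PLS1-DA decomposition
#'
#' @slot center feature means; @slot yMean mean of the 0/1 class code.
#' @slot weights features x components weight matrix W (unit columns).
#' @slot xLoadings features x components loading matrix P.
#' @slot yLoadings y-loading q per component.
#' @slot scores samples x components X-score matrix T.
#' @slot ssY explained Y sum of squares per component.
#' @slot xVarRatio fraction of centered X variance per component.
#' @slot yVarRatio fraction of centered Y variance per component.
#' @export
setClass("PLSModel",
         representation(center = "numeric", yMean = "numeric",
                        weights = "matrix", xLoadings = "matrix",
                        yLoadings = "numeric", scores = "matrix",
                        ssY = "numeric", xVarRatio = "numeric",
                        yVarRatio = "numeric"))

#' OSCModel: orthogonal signal correction components
#'
#' @slot center feature means used for centering.
#' @slot weights features x components weight matrix (unit columns).
#' @slot loadings features x components removed loadings.
#' @slot scores samples x components removed scores (training data).
#' @slot scoreYCor |correlation| of each removed score with the centered
#'   class code (invariant: < 1e-6).
#' @slot variant character, the OSC algorithm variant name.
#' @export
setClass("OSCModel",
         representation(center = "numeric", weights = "matrix",
                        loadings = "matrix", scores = "matrix",
                        scoreYCor = "numeric", variant = "character"))

#' CVResult: cross-validated classification result
#'
#' @slot folds integer fold id per sample.
#' @slot truth true labels; @slot predicted pooled out-of-fold predictions.
#' @slot scores pooled out-of-fold CRC scores (higher = more CRC-like).
#' @slot confusion 2x2 confusion matrix (rows truth, cols predicted).
#' @slot metrics metrics panel data.frame (percent scale, full precision).
#' @slot roc data.frame of ROC points (fpr, tpr, threshold).
#' @slot auc area under the ROC curve.
#' @slot classifier,mode,seed bookkeeping of how the CV was run.
#' @export
setClass("CVResult",
         representation(folds = "integer", truth = "factor",
                        predicted = "factor", scores = "numeric",
                        confusion = "matrix", metrics = "data.frame",
                        roc = "data.frame", auc = "numeric",
                        classifier = "character", mode = "character",
                        seed = "integer"))
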