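#' @describeIn VocExperiment-class samples x features value matrix.
#' @param x a `VocExperiment`.
#' @export
setGeneric("vocMatrix", function(x) standardGeneric("vocMatrix"))

#' @export
setMethod("vocMatrix", "VocExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "area"))
})

#' @describeIn VocExperiment-class class label factor (levels CO, CRC),
#'   one per sample.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setMethod("classLabels", "VocExperiment", function(x) {
  SummarizedExperiment::colData(x)$class
})

#' @export
setMethod("show", "VocExperiment", function(object) {
  cls <- table(classLabels(object))
  cat(sprintf("VocExperiment: %d samples x %d features (%s)\n",
              ncol(object), nrow(object),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  nMiss <- sum(is.na(SummarizedExperiment::assay(object, "area")))
  if (nMiss > 0) cat(sprintf("  %d missing entries\n", nMiss))
  invisible(NULL)
})

#' Replace the value matrix of a VocExperiment
#'
#' Returns a copy of `x` whose assay holds `values` (samples x features);
#' feature names may change (e.g. after selection), sample ids and labels are
#' preserved.
#'
#' @param x a `VocExperiment`.
#' @param values samples x features numeric matrix, rows aligned with `x`.
#' @return A `VocExperiment`.
#' @export
setVocMatrix <- function(x, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(x))
    stop("values must keep one row per sample")
  VocExperiment(values, labels = as.character(classLabels(x)),
                sampleIds = colnames(x),
                featureNames = colnames(values))
}

#' Read / write the consolidated feature-matrix CSV
#'
#' The on-disk layout is: first column `sample_id`, second column `label`
#' (CO/CRC), remaining columns one per feature named by its retention-time
#' string (GC-MS) or sensor label (E-nose). Missing peaks are empty cells.
#'
#' @param path CSV file path.
#' @return `readFeatureMatrix` returns a [VocExperiment-class];
#'   `writeFeatureMatrix` invisibly returns `path`.
#' @examples
#' ve <- VocExperiment(matrix(1:6, 2, 3), c("CO", "CRC"))
#' f <- tempfile(fileext = ".csv")
#' writeFeatureMatrix(ve, f)
#' identical(vocMatrix(readFeatureMatrix(f)), vocMatrix(ve))
#' @export
readFeatureMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2], c("sample_id", "label")))
    stop("feature-matrix CSV must start with sample_id and label columns")
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  VocExperiment(values, labels = df$label, sampleIds = df$sample_id,
                featureNames = colnames(df)[-(1:2)])
}

#' @rdname readFeatureMatrix
#' @param x a `VocExperiment` to write.
#' @export
writeFeatureMatrix <- function(x, path) {
  stopifnot(is(x, "VocExperiment"))
  df <- data.frame(sample_id = colnames(x),
                   label = as.character(classLabels(x)),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(vocMatrix(x), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable '%s': %d peaks, RT %.2f-%.2f min%s\n",
              object@sampleId, nrow(object@peaks),
              suppressWarnings(min(object@peaks$rt)),
              suppressWarnings(max(object@peaks$rt)),
              if (is.na(object@isArea)) "" else
                sprintf(", IS area %.3g", object@isArea)))
  invisible(NULL)
})

#' @export
setMethod("show", "SensorRecording", function(object) {
  cat(sprintf("SensorRecording '%s'%s: %d channels, %d points, %.0f s (%s)\n",
              object@sampleId,
              if (is.na(object@label)) "" else paste0(" [", object@label, "]"),
              ncol(object@channels), length(object@time),
              diff(range(object@time)),
              paste(rle(object@phase)$values, collapse = "|")))
  invisible(NULL)
})

#' @export
setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components over %d features\n",
              ncol(object@loadings), nrow(object@loadings)))
  cat("  explained variance:",
      paste(sprintf("%.2f%%", 100 * object@varRatio), collapse = " "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel (NIPALS PLS1-DA): %d latent variables, %d features\n",
              ncol(object@weights), nrow(object@weights)))
  cat("  X variance:",
      paste(sprintf("%.2f%%", 100 * object@xVarRatio), collapse = " "), "\n")
  cat("  Y variance:",
      paste(sprintf("%.2f%%", 100 * object@yVarRatio), collapse = " "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "OSCModel", function(object) {
  cat(sprintf("OSCModel (%s): %d removed component(s), max |corr(score, y)| = %.2e\n",
              object@variant, ncol(object@weights),
              if (length(object@scoreYCor)) max(object@scoreYCor) else 0))
  invisible(NULL)
})

#' @export
setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %s, %d-fold, mode '%s', seed %d\n",
              object@classifier, max(object@folds), object@mode, object@seed))
  acc <- object@metrics$value[object@metrics$metric == "accuracy" &
                              object@metrics$class == "overall"]
  cat(sprintf("  overall accuracy %.1f%%, AUC %.3f\n", acc, object@auc))
  print(object@confusion)
  invisible(NULL)
})

## internal: run an expression with a local, restored RNG state
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}
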