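## ---------------------------------------------------------------------------
## End-to-end arms: GC-MS and E-nose pipelines with logging and reports
## ---------------------------------------------------------------------------

#' Stable hash of a pipeline configuration
#'
#' Small polynomial hash over the deparsed configuration, used so that a
#' run log identifies exactly which configuration produced it.
#' @param config any R object.
#' @return 8-character hexadecimal string.
#' @export
configHash <- function(config) {
  s <- paste(deparse(config, control = c("keepNA", "niceNames", "showAttributes")),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stageLog <- function(log, stage, inDim, outDim, ...) {
  params <- list(...)
  ptxt <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = "|"),
                         character(1))), collapse = " ")
  else ""
  c(log, sprintf("stage=%s in=%s out=%s %s", stage,
                 paste(inDim, collapse = "x"),
                 paste(outDim, collapse = "x"), ptxt))
}

#' Run the GC-MS arm end to end
#'
#' curate (drop empty features) -> impute -> normalize -> univariate
#' selection -> PCA or PLS-DA projection -> classifier -> stratified CV ->
#' report. In `"honest"` mode the normalizer, selection and projection are
#' refitted inside every training fold; in `"as_paper"` mode they are
#' fitted once on all samples before cross-validation (see
#' [crossValidate()]). Moving-average imputation is always performed
#' upstream: it is unsupervised and strictly within-column.
#'
#' @param input a [VocExperiment-class] (possibly with missing entries) or
#'   a [gcmsSimConfig()] to simulate from.
#' @param reduction `"plsda"` (default) or `"pca"`.
#' @param classifier `"knn"` (default), `"lda"`, `"lr"` or `"svm"`.
#' @param normalization normalization method (default `"autoscale"`).
#' @param alpha,kFallback selection parameters (defaults 0.05 and 13).
#' @param nLV,nPC latent variables / principal components (default 3).
#' @param kNeighbors k-NN neighbourhood size (default 5).
#' @param cvFolds number of CV folds (default 5).
#' @param mode `"as_paper"` or `"honest"`.
#' @param seed pipeline seed (fold shuffle, PERMANOVA permutations).
#' @param nPerm PERMANOVA permutations (default 999).
#' @param outDir optional output directory for matrices, metrics, ROC
#'   points and the run log.
#' @return list of class `GcmsArmResult`: `cv` ([CVResult-class]),
#'   `selection`, `vip` (named VIP scores when `reduction = "plsda"`),
#'   `model` (the projection model fitted on all samples, for reporting),
#'   `permanova`, `imputed` (the curated complete [VocExperiment-class]),
#'   `nFeaturesBeforeCuration`, `log`, `config`.
#' @export
runGcmsArm <- function(input, reduction = c("plsda", "pca"),
                       classifier = c("knn", "lda", "lr", "svm"),
                       normalization = "autoscale", alpha = 0.05,
                       kFallback = 13L, nLV = 3L, nPC = 3L, kNeighbors = 5L,
                       cvFolds = 5L, mode = c("honest", "as_paper"),
                       seed = 1L, nPerm = 999L, outDir = NULL) {
  reduction <- match.arg(reduction)
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  config <- list(arm = "gcms", reduction = reduction, classifier = classifier,
                 normalization = normalization, alpha = alpha,
                 kFallback = kFallback, nLV = nLV, nPC = nPC,
                 kNeighbors = kNeighbors, cvFolds = cvFolds, mode = mode,
                 seed = seed,
                 sim = if (inherits(input, "GcmsSimConfig")) input)
  log <- character(0)
  if (inherits(input, "GcmsSimConfig")) {
    input <- simulateGcms(input)
    log <- .stageLog(log, "simulate", c(NA, NA), dim(vocMatrix(input)),
                     seed = config$sim$seed)
  }
  stopifnot(is(input, "VocExperiment"))
  nBefore <- nrow(input)
  curated <- dropEmptyFeatures(input)
  log <- .stageLog(log, "curate", dim(vocMatrix(input)),
                   dim(vocMatrix(curated)), minPresent = 1)
  imputed <- imputeMovingAverage(curated, window = 3L)
  log <- .stageLog(log, "impute", dim(vocMatrix(curated)),
                   dim(vocMatrix(imputed)), window = 3)
  raw <- vocMatrix(imputed)
  labels <- classLabels(imputed)
  fitTransform <- function(trX, trY) {
    norm <- fitNormalizer(trX, normalization)
    z <- applyNormalizer(norm, trX)
    sel <- selectFeatures(z, trY, alpha = alpha, kFallback = kFallback,
                          varianceSource = trX)
    zSel <- z[, sel$table$selected, drop = FALSE]
    model <- if (reduction == "plsda") fitPLSDA(zSel, trY, nLV = nLV)
             else fitPCA(zSel, min(nPC, min(nrow(zSel) - 1, ncol(zSel))))
    list(norm = norm, keep = sel$table$selected, sel = sel, model = model)
  }
  applyTransform <- function(fit, x) {
    z <- applyNormalizer(fit$norm, x)[, fit$keep, drop = FALSE]
    if (is(fit$model, "PLSModel")) plsProject(fit$model, z)
    else projectPCA(fit$model, z)
  }
  cv <- crossValidate(raw, labels, classifier = classifier, folds = cvFolds,
                      seed = seed, mode = mode,
                      fitTransform = fitTransform,
                      applyTransform = applyTransform,
                      classifierArgs = if (classifier == "knn")
                        list(k = kNeighbors) else list())
  log <- .stageLog(log, "cv", dim(raw),
                   c(length(labels), if (reduction == "plsda") nLV else nPC),
                   classifier = classifier, mode = mode, folds = cvFolds,
                   seed = seed)
  ## whole-cohort fit for reporting (selection table, VIP scores, PERMANOVA)
  fitAll <- fitTransform(raw, labels)
  ## group separation is quantified on the reduced (selected, normalized)
  ## matrix, the same view the score plots are drawn from
  zSel <- applyNormalizer(fitAll$norm, raw)[, fitAll$keep, drop = FALSE]
  perma <- permanovaTest(zSel, labels, nPerm = nPerm, seed = seed)
  log <- .stageLog(log, "permanova", dim(zSel), c(1, 1),
                   F = round(perma$statistic, 3), p = perma$p.value)
  vip <- if (is(fitAll$model, "PLSModel")) vipScores(fitAll$model)
  res <- structure(list(cv = cv, selection = fitAll$sel, vip = vip,
                        model = fitAll$model, permanova = perma,
                        imputed = imputed,
                        nFeaturesBeforeCuration = nBefore,
                        log = log, config = config),
                   class = "GcmsArmResult")
  if (!is.null(outDir)) .writeArmArtifacts(res, outDir)
  res
}

#' Run the E-nose arm end to end
#'
#' segment -> Max-Min feature extraction -> OSC -> autoscale -> PCA ->
#' classifier -> stratified CV -> report. An ablation without the OSC step
#' is always computed alongside, so the drift-correction benefit is part of
#' every report.
#'
#' @param input a list of [SensorRecording-class] objects, an
#'   [enoseSimConfig()] to simulate from, or a [VocExperiment-class] of
#'   already-extracted Max-Min features.
#' @param classifier `"lda"` (default), `"knn"`, `"lr"` or `"svm"`.
#' @param nOsc OSC components removed (default 1).
#' @param nPC principal components kept (default 3).
#' @param window Max-Min feature window (see [extractMaxMin()]).
#' @param kNeighbors,cvFolds,mode,seed,outDir as in [runGcmsArm()].
#' @return list of class `EnoseArmResult`: `cv` (with OSC), `cvNoOsc`
#'   (ablation), `features` (the Max-Min [VocExperiment-class]), `osc`
#'   (whole-cohort [OSCModel-class], for reporting), `log`, `config`.
#' @export
runEnoseArm <- function(input, classifier = c("lda", "knn", "lr", "svm"),
                        nOsc = 1L, nPC = 3L,
                        window = "baseline+sample", kNeighbors = 5L,
                        cvFolds = 5L, mode = c("honest", "as_paper"),
                        seed = 1L, outDir = NULL) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  config <- list(arm = "enose", classifier = classifier, nOsc = nOsc,
                 nPC = nPC, window = window, kNeighbors = kNeighbors,
                 cvFolds = cvFolds, mode = mode, seed = seed,
                 sim = if (inherits(input, "EnoseSimConfig")) input)
  log <- character(0)
  if (inherits(input, "EnoseSimConfig")) {
    simCfg <- input
    input <- simulateEnose(simCfg)
    log <- .stageLog(log, "simulate", c(NA, NA),
                     c(length(input), simCfg$nSensors), seed = simCfg$seed)
  }
  if (is(input, "VocExperiment")) {
    features <- input
  } else {
    stopifnot(is.list(input), all(vapply(input, is, TRUE, "SensorRecording")))
    features <- buildEnoseMatrix(input, window = window)
    log <- .stageLog(log, "maxmin", c(length(input), NA),
                     dim(vocMatrix(features)), window = window)
  }
  raw <- vocMatrix(features)
  labels <- classLabels(features)
  makeTransform <- function(useOsc) {
    fitT <- function(trX, trY) {
      osc <- NULL
      z <- trX
      if (useOsc && nOsc > 0) {
        corr <- oscCorrect(trX, trY, nOsc = nOsc)
        osc <- corr$model
        z <- corr$corrected  # label-aware orthogonalized correction
      }
      norm <- fitNormalizer(z, "autoscale")
      z <- applyNormalizer(norm, z)
      pca <- fitPCA(z, min(nPC, min(nrow(z) - 1, ncol(z))))
      list(osc = osc, norm = norm, pca = pca, train = pca@scores)
    }
    applyT <- function(fit, x) {
      z <- if (is.null(fit$osc)) x else oscApply(fit$osc, x)
      projectPCA(fit$pca, applyNormalizer(fit$norm, z))
    }
    list(fit = fitT, apply = applyT)
  }
  args <- if (classifier == "knn") list(k = kNeighbors) else list()
  trOsc <- makeTransform(TRUE)
  trRaw <- makeTransform(FALSE)
  cv <- crossValidate(raw, labels, classifier = classifier, folds = cvFolds,
                      seed = seed, mode = mode, fitTransform = trOsc$fit,
                      applyTransform = trOsc$apply, classifierArgs = args)
  cvNoOsc <- crossValidate(raw, labels, classifier = classifier,
                           folds = cvFolds, seed = seed, mode = mode,
                           fitTransform = trRaw$fit,
                           applyTransform = trRaw$apply,
                           classifierArgs = args)
  log <- .stageLog(log, "cv", dim(raw), c(length(labels), nPC),
                   classifier = classifier, mode = mode, folds = cvFolds,
                   osc = nOsc, seed = seed,
                   accuracy = round(cvAccuracy(cv), 1),
                   accuracyNoOsc = round(cvAccuracy(cvNoOsc), 1))
  oscAll <- if (nOsc > 0) oscCorrect(raw, labels, nOsc = nOsc)$model
  res <- structure(list(cv = cv, cvNoOsc = cvNoOsc, features = features,
                        osc = oscAll, log = log, config = config),
                   class = "EnoseArmResult")
  if (!is.null(outDir)) .writeArmArtifacts(res, outDir)
  res
}

#' @export
print.GcmsArmResult <- function(x, ...) {
  cat("GC-MS arm (", x$config$reduction, " + ", x$config$classifier,
      ", mode ", x$config$mode, ")\n", sep = "")
  cat(sprintf("  CV accuracy %.1f%%, AUC %.3f; PERMANOVA F = %.2f (p = %.3g)\n",
              cvAccuracy(x$cv), x$cv@auc, x$permanova$statistic,
              x$permanova$p.value))
  invisible(x)
}

#' @export
print.EnoseArmResult <- function(x, ...) {
  cat("E-nose arm (OSC + PCA + ", x$config$classifier, ", mode ",
      x$config$mode, ")\n", sep = "")
  cat(sprintf("  CV accuracy %.1f%% with OSC, %.1f%% without (AUC %.3f / %.3f)\n",
              cvAccuracy(x$cv), cvAccuracy(x$cvNoOsc), x$cv@auc,
              x$cvNoOsc@auc))
  invisible(x)
}

.writeArmArtifacts <- function(res, outDir) {
  dir.create(file.path(outDir, "metrics"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "matrices"), showWarnings = FALSE)
  if (inherits(res, "GcmsArmResult")) {
    writeFeatureMatrix(res$imputed, file.path(outDir, "matrices",
                                              "imputed.csv"))
    writeSelectionResult(res$selection, file.path(outDir, "metrics",
                                                  "selection.csv"))
    if (!is.null(res$vip))
      write.csv(data.frame(feature = names(res$vip), vip = res$vip),
                file.path(outDir, "metrics", "vip.csv"), row.names = FALSE)
    writeCVResult(res$cv, file.path(outDir, "metrics"))
  } else {
    writeFeatureMatrix(res$features, file.path(outDir, "matrices",
                                               "maxmin.csv"))
    writeCVResult(res$cv, file.path(outDir, "metrics"))
    writeCVResult(res$cvNoOsc, file.path(outDir, "metrics", "no_osc"))
  }
  writeLines(c(sprintf("config_hash=%s", configHash(res$config)), res$log),
             file.path(outDir, "run.log"))
  invisible(outDir)
}
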