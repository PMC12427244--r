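## ---------------------------------------------------------------------------
## Synthetic data: GC-MS-like peak-area matrices and E-nose-like transients
## with the statistical structure the downstream analysis assumes.
## ---------------------------------------------------------------------------

#' Default informative GC-MS features
#'
#' The thirteen discriminant retention-time features used as the default
#' informative set of the GC-MS simulator, with their group geometric-mean
#' peak areas (arbitrary area units) in the control (CO) and case (CRC)
#' groups.
#'
#' @return data.frame with columns `rt` (retention-time string), `meanCO`,
#'   `meanCRC`.
#' @export
defaultInformativeFeatures <- function() {
  data.frame(
    rt = c("10.7", "20.7", "17.8", "10.8", "18.3", "6.7", "24.4",
           "16.7", "17.9", "24", "24.6", "24.7", "8.4"),
    meanCO  = c(1.87e6, 1.83e6, 9.22e5, 5.58e6, 4.55e5, 2.90e8, 1.07e6,
                2.51e6, 3.65e5, 2.65e5, 1.34e5, 4.22e5, 5.27e5),
    meanCRC = c(8.39e5, 3.80e5, 7.48e5, 8.57e6, 2.17e5, 1.70e8, 1.71e6,
                2.04e6, 2.30e5, 1.40e5, 2.04e5, 9.52e4, 2.40e6),
    stringsAsFactors = FALSE)
}

## the simulator's retention-time grid: 187 values covering the informative
## RTs, 0.1-min spaced as after one-decimal rounding
.defaultRtGrid <- function(nFeatures = 187L) {
  rts <- seq(6.1, by = 0.1, length.out = nFeatures)
  formatRt(rts)
}

#' Format retention times as feature-name strings
#'
#' One-decimal formatting that drops trailing zeros the same way the curation
#' layer does, so simulated and curated feature names agree (`"24"` not
#' `"24.0"`).
#' @param rt numeric retention times.
#' @return character vector.
#' @export
formatRt <- function(rt) {
  as.character(round(rt + sign(rt) * 1e-9, 1))
}

#' GC-MS simulation configuration
#'
#' Defaults mirror the study conditions this package targets: 34 control and
#' 31 case samples over 187 retention-time features, 13 of which are
#' informative with the group geometric means of
#' [defaultInformativeFeatures()]. Peak areas are lognormal (positive,
#' right-skewed) with multiplicative noise of coefficient of variation
#' `noiseCV`; missingness is completely at random. The default
#' `noiseCV = 2` is calibrated so that the simulated cohort has roughly the
#' discrimination difficulty the pipeline is designed for (cross-validated
#' accuracies in the 70-90% range rather than a saturated 100%); biological
#' peak-area CVs of this order are typical of untargeted volatilomics.
#'
#' @param nCO,nCRC sample counts per group.
#' @param nFeatures total number of retention-time features.
#' @param informative data.frame with columns `rt`, `meanCO`, `meanCRC`
#'   (geometric means, area units). `rt` values must be on the simulator's
#'   retention-time grid. Empty data.frame gives a null (no-signal) dataset.
#' @param noiseCV coefficient of variation of the multiplicative lognormal
#'   noise (sigma on the log scale is `sqrt(log(1 + noiseCV^2))`).
#' @param missingRate fraction of entries set missing, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a validated list of class `GcmsSimConfig`.
#' @export
gcmsSimConfig <- function(nCO = 34L, nCRC = 31L, nFeatures = 187L,
                          informative = defaultInformativeFeatures(),
                          noiseCV = 2.0, missingRate = 0.05, seed = 1L) {
  stopifnot(nCO >= 1, nCRC >= 1, nFeatures >= 1,
            noiseCV >= 0, missingRate >= 0, missingRate < 1)
  informative <- as.data.frame(informative)
  if (nrow(informative) > 0) {
    stopifnot(all(c("rt", "meanCO", "meanCRC") %in% colnames(informative)))
    if (any(informative$meanCO <= 0) || any(informative$meanCRC <= 0))
      stop("informative feature means must be positive")
  }
  if (nrow(informative) > nFeatures)
    stop("more informative features than total features")
  grid <- .defaultRtGrid(nFeatures)
  if (nrow(informative) > 0 && !all(informative$rt %in% grid))
    stop("informative rt not on the simulated retention-time grid: ",
         paste(setdiff(informative$rt, grid), collapse = ", "))
  structure(list(nCO = as.integer(nCO), nCRC = as.integer(nCRC),
                 nFeatures = as.integer(nFeatures),
                 informative = informative, noiseCV = noiseCV,
                 missingRate = missingRate, seed = as.integer(seed)),
            class = "GcmsSimConfig")
}

#' Simulate a GC-MS peak-area feature matrix
#'
#' Uninformative features share one lognormal distribution across groups
#' (feature-specific geometric means drawn log-uniformly between 1e5 and 1e7
#' area units); each informative feature has the configured group geometric
#' means. All entries are positive before missingness is applied. Identical
#' configurations (including seed) give identical output.
#'
#' @param config a [gcmsSimConfig()] object.
#' @return A [VocExperiment-class] of dimension `(nCO + nCRC) x nFeatures`.
#' @examples
#' ve <- simulateGcms(gcmsSimConfig(seed = 7))
#' table(classLabels(ve))
#' @export
simulateGcms <- function(config) {
  stopifnot(inherits(config, "GcmsSimConfig"))
  withSeed(config$seed, {
    n <- config$nCO + config$nCRC
    p <- config$nFeatures
    labels <- rep(.vocClasses, c(config$nCO, config$nCRC))
    featNames <- .defaultRtGrid(p)
    sigma <- sqrt(log(1 + config$noiseCV^2))
    ## one geometric mean per feature, identical in both groups
    logGm <- runif(p, log(1e5), log(1e7))
    logMean <- matrix(rep(logGm, each = n), n, p)
    if (nrow(config$informative) > 0) {
      idx <- match(config$informative$rt, featNames)
      isCrc <- labels == "CRC"
      for (j in seq_along(idx)) {
        logMean[!isCrc, idx[j]] <- log(config$informative$meanCO[j])
        logMean[isCrc, idx[j]] <- log(config$informative$meanCRC[j])
      }
    }
    values <- exp(logMean + sigma * matrix(rnorm(n * p), n, p))
    if (config$missingRate > 0)
      values[matrix(runif(n * p) < config$missingRate, n, p)] <- NA_real_
    ids <- c(sprintf("CO%03d", seq_len(config$nCO)),
             sprintf("CRC%03d", seq_len(config$nCRC)))
    VocExperiment(values, labels, sampleIds = ids, featureNames = featNames)
  })
}

#' E-nose sensor labels
#'
#' The 14 channel labels of the MEMS metal-oxide sensor array, in board
#' order.
#' @return character vector of length 14.
#' @export
enoseSensorLabels <- function() {
  c("BMU1", "BMU5", "CCU2", "CCU6", "SGOH", "SGH2", "SGO7",
    "SGH7", "VRED", "VOXU", "VNH3", "VNO2", "VOUT", "VN12")
}

## fixed sensor properties of the simulator (signal units): baseline level,
## control-group plateau amplitude, and the case-minus-control amplitude
## shift. The shift is close to uniform across sensors so that the class
## signature is strongly collinear with the shared drift direction -- the
## regime orthogonal signal correction exists for.
.enoseBaseLevels <- c(0.40, 0.50, 0.60, 0.70, 0.80, 0.90, 1.00,
                      1.10, 1.20, 1.30, 1.40, 1.50, 1.60, 1.70)
.enoseAmpCO <- c(1.20, 0.85, 1.60, 1.45, 0.95, 1.10, 0.90,
                 1.05, 1.80, 1.55, 0.75, 1.30, 1.70, 1.00)
.enoseAmpShift <- 0.25 + c(0.012, -0.016, 0.020, -0.008, 0.016, -0.020, 0.008,
                           0.020, -0.012, 0.016, -0.008, 0.012, -0.020, 0.008)

#' E-nose simulation configuration
#'
#' Defaults emulate the acquisition protocol the pipeline targets: 35 control
#' and 33 case recordings from a 14-sensor array sampled at 1 Hz over a
#' 60 s baseline phase followed by a 120 s sample phase. Each channel is a
#' baseline level plus a class-dependent response plateau during the sample
#' phase, plus a shared linear upward drift whose slope is drawn once per
#' sample from a half-normal distribution (the class-orthogonal nuisance OSC
#' removes; session drift of heated metal-oxide sensors is monotone), plus
#' additive Gaussian noise.
#'
#' @param nCO,nCRC recording counts per group.
#' @param nSensors number of channels (default 14, the full array).
#' @param sampleRate sampling rate in Hz.
#' @param baselineS,sampleS phase durations in seconds.
#' @param ampCO,ampCRC per-sensor mean plateau amplitudes (signal units) for
#'   each class; recycled to `nSensors`.
#' @param driftSlopeSD scale of the half-normal per-sample drift slope
#'   (signal units per second). The default 0.01 makes the drift excursion
#'   over a recording (~1.8 units) much larger than the class amplitude
#'   difference (~0.25 units): a drift-dominated device.
#' @param noiseSD additive noise standard deviation.
#' @param seed integer RNG seed.
#' @return a validated list of class `EnoseSimConfig`.
#' @export
enoseSimConfig <- function(nCO = 35L, nCRC = 33L, nSensors = 14L,
                           sampleRate = 1, baselineS = 60, sampleS = 120,
                           ampCO = .enoseAmpCO[seq_len(nSensors)],
                           ampCRC = (.enoseAmpCO + .enoseAmpShift)[seq_len(nSensors)],
                           driftSlopeSD = 0.01, noiseSD = 0.15, seed = 1L) {
  stopifnot(nCO >= 1, nCRC >= 1, nSensors >= 1, sampleRate > 0,
            baselineS > 0, sampleS > 0, driftSlopeSD >= 0, noiseSD >= 0)
  ampCO <- rep_len(as.numeric(ampCO), nSensors)
  ampCRC <- rep_len(as.numeric(ampCRC), nSensors)
  if (any(ampCO < 0) || any(ampCRC < 0))
    stop("amplitudes must be non-negative")
  structure(list(nCO = as.integer(nCO), nCRC = as.integer(nCRC),
                 nSensors = as.integer(nSensors), sampleRate = sampleRate,
                 baselineS = baselineS, sampleS = sampleS,
                 ampCO = ampCO, ampCRC = ampCRC,
                 driftSlopeSD = driftSlopeSD, noiseSD = noiseSD,
                 seed = as.integer(seed)),
            class = "EnoseSimConfig")
}

#' Simulate E-nose recordings
#'
#' One [SensorRecording-class] per sample. Channel `c` of sample `i` at time
#' `t` is
#' `base_c + A_c(class_i) * [t in sample phase] + s_i * t + noise`, with the
#' drift slope `s_i ~ N(0, driftSlopeSD^2)` drawn once per sample and applied
#' identically to every channel and both classes. Seed-deterministic.
#'
#' @param config an [enoseSimConfig()] object.
#' @return list of [SensorRecording-class] objects, with a `driftSlope`
#'   attribute recording each sample's drift slope.
#' @examples
#' recs <- simulateEnose(enoseSimConfig(nCO = 3, nCRC = 3))
#' recs[[1]]
#' @export
simulateEnose <- function(config) {
  stopifnot(inherits(config, "EnoseSimConfig"))
  withSeed(config$seed, {
    n <- config$nCO + config$nCRC
    labels <- rep(.vocClasses, c(config$nCO, config$nCRC))
    ids <- c(sprintf("CO%03d", seq_len(config$nCO)),
             sprintf("CRC%03d", seq_len(config$nCRC)))
    dt <- 1 / config$sampleRate
    time <- seq(0, config$baselineS + config$sampleS - dt, by = dt)
    phase <- ifelse(time < config$baselineS, "baseline", "sample")
    sensors <- enoseSensorLabels()[seq_len(config$nSensors)]
    if (config$nSensors > 14)
      sensors <- c(sensors, sprintf("X%02d", seq_len(config$nSensors - 14)))
    base <- rep_len(.enoseBaseLevels, config$nSensors)
    ## half-normal: session drift of heated MOX sensors is monotone upward,
    ## so the Max-Min amplitude is exactly A + slope * T in the noiseless case
    slopes <- abs(rnorm(n, 0, config$driftSlopeSD))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      amp <- if (labels[i] == "CRC") config$ampCRC else config$ampCO
      ch <- outer(as.numeric(phase == "sample"), amp) +
        matrix(rep(base, each = length(time)), ncol = config$nSensors) +
        slopes[i] * time +
        config$noiseSD * matrix(rnorm(length(time) * config$nSensors),
                                ncol = config$nSensors)
      colnames(ch) <- sensors
      recs[[i]] <- sensorRecording(ids[i], time, ch, phase = phase,
                                   label = labels[i])
    }
    attr(recs, "driftSlope") <- slopes
    recs
  })
}
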