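## ---------------------------------------------------------------------------
## E-nose transients: phase segmentation and Max-Min amplitude features
## ---------------------------------------------------------------------------

#' Segment an E-nose recording into acquisition phases
#'
#' Tags each timestamp by elapsed time since the start of the recording:
#' an optional stabilization stretch, then `baselineS` seconds of baseline,
#' then `sampleS` seconds of sample exposure. Anything after the sample
#' phase is purge and is truncated. Boundaries are assigned by time, not by
#' index, so irregular sampling is handled correctly.
#'
#' @param rec a [SensorRecording-class] (its existing phase tags are
#'   ignored).
#' @param baselineS,sampleS phase durations in seconds (defaults 60 and
#'   120).
#' @param stabilizeS stabilization duration preceding the baseline
#'   (default 0: the recording starts at the baseline phase).
#' @return A [SensorRecording-class] with phases assigned and trailing
#'   purge removed.
#' @export
segmentPhases <- function(rec, baselineS = 60, sampleS = 120,
                          stabilizeS = 0) {
  stopifnot(is(rec, "SensorRecording"), baselineS > 0, sampleS > 0,
            stabilizeS >= 0)
  el <- rec@time - rec@time[1]
  needed <- stabilizeS + baselineS + sampleS
  covered <- el[length(el)] + median(diff(rec@time))  # last sampling interval
  if (length(el) < 2 || covered < needed)
    stop(sprintf("recording covers %.1f s; %.1f s required", covered, needed))
  phase <- ifelse(el < stabilizeS, "stabilize",
           ifelse(el < stabilizeS + baselineS, "baseline",
           ifelse(el < needed, "sample", "purge")))
  keep <- phase != "purge"
  new("SensorRecording", sampleId = rec@sampleId, label = rec@label,
      time = rec@time[keep], phase = phase[keep],
      channels = rec@channels[keep, , drop = FALSE])
}

#' Max-Min response amplitude per sensor
#'
#' For each channel, the difference between the maximum and minimum recorded
#' signal over the feature window. The default window spans baseline plus
#' sample phases so the baseline-to-plateau excursion is captured;
#' `window = "sample"` restricts to the exposure phase only. Stabilization
#' and purge samples are never included.
#'
#' @param rec a segmented [SensorRecording-class].
#' @param window `"baseline+sample"` (default) or `"sample"`.
#' @return named non-negative numeric vector, one amplitude per sensor.
#' @examples
#' r <- sensorRecording("s", 0:2, matrix(c(0.2, 0.9, 0.5), 3, 1,
#'                      dimnames = list(NULL, "BMU1")))
#' extractMaxMin(r)
#' @export
extractMaxMin <- function(rec, window = c("baseline+sample", "sample")) {
  stopifnot(is(rec, "SensorRecording"))
  window <- match.arg(window)
  keep <- if (window == "sample") rec@phase == "sample"
          else rec@phase %in% c("baseline", "sample")
  if (!any(keep)) stop("empty feature window")
  ch <- rec@channels[keep, , drop = FALSE]
  apply(ch, 2, max) - apply(ch, 2, min)
}

#' Assemble Max-Min features into a feature matrix
#'
#' @param recordings list of segmented, labeled [SensorRecording-class]
#'   objects with identical channel sets.
#' @param window passed to [extractMaxMin()].
#' @return A [VocExperiment-class], samples x sensors.
#' @export
buildEnoseMatrix <- function(recordings, window = "baseline+sample") {
  stopifnot(length(recordings) >= 1)
  sensors <- colnames(recordings[[1]]@channels)
  for (r in recordings)
    if (!identical(colnames(r@channels), sensors))
      stop("inconsistent channel sets across recordings")
  values <- t(vapply(recordings, extractMaxMin, numeric(length(sensors)),
                     window = window))
  labels <- vapply(recordings, function(r) r@label, character(1))
  if (anyNA(labels)) stop("all recordings must carry a class label")
  ids <- vapply(recordings, function(r) r@sampleId, character(1))
  VocExperiment(values, labels, sampleIds = ids, featureNames = sensors)
}

#' Read / write a sensor-recording CSV
#'
#' Layout: optional comment header `# sample_id=<id>,label=<CO|CRC>`, then
#' columns `time_s`, `phase`, followed by one column per sensor label.
#'
#' @param path CSV path.
#' @return `readSensorRecording` returns a [SensorRecording-class].
#' @export
readSensorRecording <- function(path) {
  first <- readLines(path, n = 1L)
  sampleId <- basename(path); label <- NA_character_
  if (startsWith(first, "#")) {
    for (p in strsplit(strsplit(sub("^#\\s*", "", first), ",")[[1]], "=")) {
      if (p[1] == "sample_id") sampleId <- p[2]
      if (p[1] == "label") label <- p[2]
    }
  }
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  stopifnot(all(c("time_s", "phase") %in% colnames(df)))
  ch <- as.matrix(df[, setdiff(colnames(df), c("time_s", "phase")),
                     drop = FALSE])
  storage.mode(ch) <- "double"
  sensorRecording(sampleId, df$time_s, ch, phase = df$phase, label = label)
}

#' @rdname readSensorRecording
#' @param rec a [SensorRecording-class] to write.
#' @export
writeSensorRecording <- function(rec, path) {
  stopifnot(is(rec, "SensorRecording"))
  hdr <- sprintf("# sample_id=%s%s", rec@sampleId,
                 if (is.na(rec@label)) "" else sprintf(",label=%s", rec@label))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(time_s = rec@time, phase = rec@phase, check.names = FALSE)
  df <- cbind(df, as.data.frame(rec@channels, check.names = FALSE))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
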