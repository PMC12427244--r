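## ---------------------------------------------------------------------------
## GC-MS curation: per-sample peak tables -> consolidated feature matrix
## ---------------------------------------------------------------------------

## half-away-from-zero rounding; base round() uses banker's rounding which is
## not reproducible across report formats
roundHalfAway <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round retention times and merge redundant peaks
#'
#' Retention times are rounded half-away-from-zero to `decimals` places so
#' that redundant peaks of the same compound collapse onto one retention-time
#' feature; peaks sharing a rounded RT are merged with `mergeRule` (`"sum"`,
#' the default, conserves total abundance; `"max"` keeps the largest peak).
#' Output RTs are strictly increasing and unique.
#'
#' @param table a [PeakTable-class].
#' @param decimals non-negative number of decimal places (default 1).
#' @param mergeRule `"sum"` or `"max"`.
#' @return A [PeakTable-class] with rounded, unique RTs.
#' @examples
#' pt <- peakTable("a", rt = c(10.68, 10.74), area = c(100, 50))
#' roundAndMerge(pt)@peaks
#' @export
roundAndMerge <- function(table, decimals = 1L, mergeRule = c("sum", "max")) {
  stopifnot(is(table, "PeakTable"), decimals >= 0)
  mergeRule <- match.arg(mergeRule)
  pk <- table@peaks
  rt <- roundHalfAway(pk$rt, decimals)
  key <- factor(formatRt(rt), levels = unique(formatRt(sort(unique(rt)))))
  area <- tapply(pk$area, key, if (mergeRule == "sum") sum else max)
  new("PeakTable", sampleId = table@sampleId,
      peaks = data.frame(rt = sort(unique(rt)), area = as.numeric(area)),
      isArea = table@isArea)
}

#' Consolidate per-sample peak tables into one feature matrix
#'
#' The feature set is the union of all (rounded) retention times across
#' samples, sorted ascending. A sample with no peak at some RT gets a missing
#' entry (`NA`), not zero: an absent peak is unobserved, and is handled later
#' by imputation.
#'
#' @param tables list of rounded [PeakTable-class] objects.
#' @param labels class labels aligned with `tables`.
#' @return A [VocExperiment-class], samples x union-of-RTs, possibly with
#'   missing entries.
#' @export
consolidatePeakTables <- function(tables, labels) {
  stopifnot(length(tables) >= 1, length(labels) == length(tables))
  ids <- vapply(tables, function(t) t@sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  allRt <- sort(unique(unlist(lapply(tables, function(t) t@peaks$rt))))
  featNames <- formatRt(allRt)
  if (anyDuplicated(featNames))
    stop("retention times collide after formatting; round tables first")
  values <- matrix(NA_real_, length(tables), length(allRt),
                   dimnames = list(ids, featNames))
  for (i in seq_along(tables)) {
    pk <- tables[[i]]@peaks
    values[i, match(formatRt(pk$rt), featNames)] <- pk$area
  }
  VocExperiment(values, labels, sampleIds = ids, featureNames = featNames)
}

#' Drop features without relevant signal
#'
#' Removes retention-time columns with fewer than `minPresent` non-missing,
#' non-zero entries across samples; rows are untouched.
#'
#' @param x a [VocExperiment-class].
#' @param minPresent minimum number of observed positive entries a feature
#'   must have to be kept (default 1).
#' @return A [VocExperiment-class] with the empty features removed.
#' @export
dropEmptyFeatures <- function(x, minPresent = 1L) {
  stopifnot(is(x, "VocExperiment"), minPresent >= 1)
  v <- vocMatrix(x)
  present <- colSums(!is.na(v) & v != 0)
  keep <- present >= minPresent
  if (!any(keep)) stop("all features removed; no relevant signal")
  setVocMatrix(x, v[, keep, drop = FALSE])
}

#' Normalize peak areas to the internal standard
#'
#' Divides each sample's row by its internal-standard (limonene) peak area,
#' removing run-to-run injection and detection variation. The pipeline leaves
#' this off by default: the internal standard is used as a comparability
#' check, and quantitative division is an explicit opt-in.
#'
#' @param x a [VocExperiment-class].
#' @param isAreas named (or positionally aligned) per-sample internal-standard
#'   areas, all positive.
#' @return A [VocExperiment-class] with each row scaled by `1 / isArea`.
#' @export
normalizeToInternalStandard <- function(x, isAreas) {
  stopifnot(is(x, "VocExperiment"))
  if (!is.null(names(isAreas))) isAreas <- isAreas[colnames(x)]
  if (length(isAreas) != ncol(x))
    stop("need one internal-standard area per sample")
  bad <- which(is.na(isAreas) | isAreas <= 0)
  if (length(bad) > 0)
    stop("missing or non-positive internal-standard area for sample(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  setVocMatrix(x, vocMatrix(x) / as.numeric(isAreas))
}

#' Split a feature matrix back into per-sample peak tables
#'
#' Inverse of [consolidatePeakTables()]: missing entries become absent peaks.
#' Round-tripping `consolidatePeakTables(splitPeakTables(x))` reproduces `x`.
#'
#' @param x a [VocExperiment-class] whose feature names parse as retention
#'   times.
#' @return list of [PeakTable-class] objects.
#' @export
splitPeakTables <- function(x) {
  stopifnot(is(x, "VocExperiment"))
  v <- vocMatrix(x)
  rt <- as.numeric(colnames(v))
  if (anyNA(rt)) stop("feature names do not parse as retention times")
  lapply(seq_len(nrow(v)), function(i) {
    obs <- !is.na(v[i, ])
    peakTable(rownames(v)[i], rt = rt[obs], area = v[i, obs])
  })
}

#' Read / write a per-sample peak-table CSV
#'
#' Layout: optional comment header `# sample_id=<id>,is_area=<area>`, then
#' columns `rt_min,area`.
#'
#' @param path CSV path.
#' @param sampleId sample id used if the file has no header comment.
#' @return `readPeakTable` returns a [PeakTable-class].
#' @export
readPeakTable <- function(path, sampleId = basename(path)) {
  first <- readLines(path, n = 1L)
  isArea <- NA_real_
  if (startsWith(first, "#")) {
    kv <- strsplit(sub("^#\\s*", "", first), ",")[[1]]
    kv <- strsplit(kv, "=")
    for (p in kv) {
      if (p[1] == "sample_id") sampleId <- p[2]
      if (p[1] == "is_area") isArea <- as.numeric(p[2])
    }
  }
  df <- read.csv(path, comment.char = "#")
  stopifnot(all(c("rt_min", "area") %in% colnames(df)))
  peakTable(sampleId, rt = df$rt_min, area = df$area, isArea = isArea)
}

#' @rdname readPeakTable
#' @param table a [PeakTable-class] to write.
#' @export
writePeakTable <- function(table, path) {
  stopifnot(is(table, "PeakTable"))
  hdr <- sprintf("# sample_id=%s%s", table@sampleId,
                 if (is.na(table@isArea)) ""
                 else sprintf(",is_area=%.10g", table@isArea))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(data.frame(rt_min = table@peaks$rt, area = table@peaks$area),
            con, row.names = FALSE)
  invisible(path)
}
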