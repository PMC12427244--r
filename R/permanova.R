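## ---------------------------------------------------------------------------
## Permutational multivariate analysis of variance (pseudo-F on distances)
## ---------------------------------------------------------------------------

## sums of squares from a squared-distance matrix: total = sum_{i<j} d2/n,
## within = sum over groups of the within-group pair sums / group size
.permanovaF <- function(d2, groupIdx, groupSizes) {
  n <- nrow(d2)
  g <- length(groupSizes)
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssWithin <- 0
  for (k in seq_len(g)) {
    i <- groupIdx[[k]]
    dk <- d2[i, i, drop = FALSE]
    ssWithin <- ssWithin + sum(dk[upper.tri(dk)]) / groupSizes[k]
  }
  ssBetween <- ssTotal - ssWithin
  (ssBetween / (g - 1)) / (ssWithin / (n - g))
}

#' PERMANOVA: permutation test of multivariate group separation
#'
#' Pseudo-F computed from the Euclidean distance matrix (the
#' distance-partitioning formulation):
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`, with significance
#' from seeded random label permutations:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + nPerm)`.
#'
#' @param x a [VocExperiment-class] or complete samples x features matrix.
#' @param labels class labels (ignored for a VocExperiment); every group
#'   needs at least 2 samples.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `permanovaResult`: `statistic` (pseudo-F),
#'   `p.value`, `nPerm`, `seed`.
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 2), 10))
#' permanovaTest(x, rep(c("CO", "CRC"), each = 10), seed = 1)
#' @export
setGeneric("permanovaTest", function(x, labels = NULL, nPerm = 999L,
                                     seed = NULL)
  standardGeneric("permanovaTest"))

#' @export
setMethod("permanovaTest", "VocExperiment",
          function(x, labels = NULL, nPerm = 999L, seed = NULL)
  permanovaTest(vocMatrix(x), classLabels(x), nPerm, seed))

#' @export
setMethod("permanovaTest", "matrix",
          function(x, labels = NULL, nPerm = 999L, seed = NULL) {
  stopifnot(!anyNA(x), nPerm >= 1)
  labels <- factor(labels)
  labels <- droplevels(labels)
  stopifnot(length(labels) == nrow(x))
  sizes <- table(labels)
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  d2 <- as.matrix(stats::dist(x))^2
  lv <- levels(labels)
  idx <- lapply(lv, function(l) which(labels == l))
  fObs <- .permanovaF(d2, idx, as.numeric(sizes))
  n <- nrow(x)
  fPerm <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    perm <- sample.int(n)
    .permanovaF(d2, lapply(idx, function(i) perm[i]), as.numeric(sizes))
  }, numeric(1)))
  structure(list(statistic = fObs,
                 p.value = (1 + sum(fPerm >= fObs)) / (1 + nPerm),
                 nPerm = as.integer(nPerm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "permanovaResult")
})

#' @export
print.permanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean): pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$statistic, x$p.value, x$nPerm))
  invisible(x)
}
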