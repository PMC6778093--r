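#' Enrichment-call parameters
#'
#' @param foldThreshold per-replicate fold threshold over the control
#'   (> 1, default 2); the comparison is strict (`>`): a peak must be
#'   *more than* `foldThreshold`-fold enriched in a replicate for that
#'   replicate to count.
#' @param pseudocount additive pseudocount on both interval means.
#' @param requireAllReplicates with the default `TRUE`, a peak is
#'   `enriched` only when every replicate exceeds the threshold and
#'   `partially_enriched` when only some do; with `FALSE` a single
#'   exceeding replicate suffices for `enriched`.
#' @return A validated parameter list of class `EnrichmentParams`.
#' @export
enrichmentParams <- function(foldThreshold = 2, pseudocount = 0.1,
                             requireAllReplicates = TRUE) {
  if (!is.numeric(foldThreshold) || foldThreshold <= 1) {
    stopDomain("'foldThreshold' must be > 1")
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stopDomain("'pseudocount' must be >= 0")
  }
  structure(
    list(
      foldThreshold = foldThreshold, pseudocount = pseudocount,
      requireAllReplicates = isTRUE(requireAllReplicates)
    ),
    class = "EnrichmentParams"
  )
}

asEnrichmentParams <- function(params) {
  if (inherits(params, "EnrichmentParams")) return(params)
  do.call(enrichmentParams, as.list(params))
}

#' Fold change of one peak against the control library
#'
#' Returns `(mean pull-down coverage over the peak + eps) /
#' (mean control coverage over the peak + eps)`. Both tracks must be
#' library-size normalized and on the peak's strand.
#'
#' @param peak a single-range [GenomicRanges::GRanges] (or anything with
#'   `start`/`end` accessors) on the tracks' strand.
#' @param pulldown,control normalized [CoverageTrack-class] objects.
#' @param eps additive pseudocount.
#' @return A positive number.
#' @export
peakFoldChange <- function(peak, pulldown, control, eps = 0.1) {
  if (!isNormalized(pulldown) || !isNormalized(control)) {
    stopState("fold changes require library-size normalized tracks")
  }
  if (strand(pulldown) != strand(control) ||
      trackLength(pulldown) != trackLength(control)) {
    stopIncompatible("pull-down and control tracks do not match")
  }
  st <- as.integer(BiocGenerics::start(peak))[1L]
  en <- as.integer(BiocGenerics::end(peak))[1L]
  if (length(peak) > 0 && !is.na(as.character(BiocGenerics::strand(peak))[1L])) {
    ps <- as.character(BiocGenerics::strand(peak))[1L]
    if (ps %in% c("+", "-") && ps != strand(pulldown)) {
      stopIncompatible("peak strand does not match track strand")
    }
  }
  if (st < 1L || en > trackLength(pulldown)) {
    stopCoordinate("peak [", st, ",", en, "] outside track")
  }
  idx <- st:en
  (mean(coverageValues(pulldown)[idx]) + eps) /
    (mean(coverageValues(control)[idx]) + eps)
}

#' Classify peaks by replicate-consensus enrichment over the control
#'
#' Computes, per peak, the fold change of each pull-down replicate against
#' the single control library and assigns a three-way status: `enriched`
#' when every replicate is more than `foldThreshold`-fold above the
#' control, `partially_enriched` when some but not all are, and
#' `not_enriched` otherwise.
#'
#' @param peaks a [GenomicRanges::GRanges] of called peaks, all on the
#'   tracks' strand (see [callPeaks()]).
#' @param pulldownReps list of >= 1 normalized replicate
#'   [CoverageTrack-class] objects.
#' @param control the normalized control [CoverageTrack-class].
#' @param params an [enrichmentParams()] list.
#' @return `peaks` with added metadata columns `fold_rep1..n` (one per
#'   replicate) and `status` (factor with the three levels above).
#' @export
classifyPeaks <- function(peaks, pulldownReps, control,
                          params = enrichmentParams()) {
  params <- asEnrichmentParams(params)
  if (is(pulldownReps, "CoverageTrack")) pulldownReps <- list(pulldownReps)
  if (!length(pulldownReps)) stopDomain("need at least one pull-down replicate")
  checkSameShape(c(pulldownReps, list(control)))
  folds <- vapply(pulldownReps, function(rep) {
    vapply(seq_along(peaks), function(k) {
      peakFoldChange(peaks[k], rep, control, eps = params$pseudocount)
    }, numeric(1))
  }, numeric(length(peaks)))
  if (is.null(dim(folds))) {
    folds <- matrix(folds, nrow = length(peaks), ncol = length(pulldownReps))
  }
  exceeds <- folds > params$foldThreshold
  nHit <- rowSums(exceeds)
  nRep <- length(pulldownReps)
  status <- rep("not_enriched", length(peaks))
  if (params$requireAllReplicates) {
    status[nHit == nRep] <- "enriched"
    status[nHit > 0 & nHit < nRep] <- "partially_enriched"
  } else {
    status[nHit > 0] <- "enriched"
  }
  for (j in seq_len(nRep)) {
    S4Vectors::mcols(peaks)[[paste0("fold_rep", j)]] <- folds[, j]
  }
  S4Vectors::mcols(peaks)$status <- factor(
    status, levels = c("enriched", "partially_enriched", "not_enriched")
  )
  peaks
}
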