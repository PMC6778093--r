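#' Peak-calling parameters
#'
#' Parameters of the sliding-window fold-change peak caller. A boundary is
#' placed where the mean coverage over two `window` nt ranges, separated
#' by a `spacer` nt gap, differs by at least `fold`; called intervals must
#' additionally reach `minCovFrac` of the dataset-wide mean coverage per
#' nucleotide. Defaults are the study settings: window 5 nt, spacer 10 nt,
#' fold change 1.5, coverage fraction 0.2.
#'
#' @param window width of each comparison window in nt (>= 1).
#' @param spacer gap between the two windows in nt (>= 0).
#' @param fold boundary fold-change threshold (> 1); comparison is `>=`.
#' @param minCovFrac minimum peak mean coverage as a fraction of the
#'   dataset mean coverage per nucleotide, in (0, 1]; comparison is `>=`.
#' @param pseudocount additive pseudocount on both window means, guarding
#'   ratios against zero background. Use 0 on strictly positive tracks.
#' @param minPeakLen minimum peak length in nt.
#' @param circular treat the genome as circular (windows wrap)?
#' @param closeOpenPeaks close a start with no downstream end at the track
#'   end (default: discard it)?
#' @return A validated parameter list of class `PeakCallParams`.
#' @export
peakCallParams <- function(window = 5L, spacer = 10L, fold = 1.5,
                           minCovFrac = 0.2, pseudocount = 0.1,
                           minPeakLen = 1L, circular = FALSE,
                           closeOpenPeaks = FALSE) {
  window <- as.integer(window)
  spacer <- as.integer(spacer)
  minPeakLen <- as.integer(minPeakLen)
  if (is.na(window) || window < 1L) stopDomain("'window' must be >= 1")
  if (is.na(spacer) || spacer < 0L) stopDomain("'spacer' must be >= 0")
  if (!is.numeric(fold) || fold <= 1) stopDomain("'fold' must be > 1")
  if (!is.numeric(minCovFrac) || minCovFrac <= 0 || minCovFrac > 1) {
    stopDomain("'minCovFrac' must be in (0, 1]")
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stopDomain("'pseudocount' must be >= 0")
  }
  if (is.na(minPeakLen) || minPeakLen < 1L) {
    stopDomain("'minPeakLen' must be >= 1")
  }
  structure(
    list(
      window = window, spacer = spacer, fold = fold,
      minCovFrac = minCovFrac, pseudocount = pseudocount,
      minPeakLen = minPeakLen, circular = isTRUE(circular),
      closeOpenPeaks = isTRUE(closeOpenPeaks)
    ),
    class = "PeakCallParams"
  )
}

asPeakCallParams <- function(params) {
  if (inherits(params, "PeakCallParams")) return(params)
  do.call(peakCallParams, as.list(params))
}

#' Scan a coverage track for peak boundary candidates
#'
#' At every evaluable position the mean coverage of two `window`-nt ranges
#' separated by `spacer` nt is compared as a ratio (high side over low
#' side, both sides offset by `pseudocount`). Position `i` is a raw start
#' candidate when the window starting at `i` exceeds the upstream window
#' by at least `fold`; position `j` is a raw end candidate when the window
#' ending at `j` exceeds the downstream window likewise. Maximal runs of
#' consecutive raw candidates of one kind collapse to the single position
#' of maximal fold; tied start candidates collapse to the leftmost and
#' tied end candidates to the rightmost position, so on a clean step the
#' retained boundaries are exactly the first and last elevated base.
#'
#' @param track a [CoverageTrack-class].
#' @param params a [peakCallParams()] list.
#' @return A `data.frame` with columns `position`, `kind` (`"start"` or
#'   `"end"`) and `fold`, sorted by position. Tracks shorter than
#'   `2 * window + spacer` yield no candidates.
#' @export
scanBoundaries <- function(track, params = peakCallParams()) {
  stopifnot(is(track, "CoverageTrack"))
  params <- asPeakCallParams(params)
  v <- coverageValues(track)
  L <- length(v)
  w <- params$window
  s <- params$spacer
  eps <- params$pseudocount
  empty <- data.frame(
    position = integer(0), kind = character(0), fold = numeric(0)
  )
  if (L < 2L * w + s) return(empty)

  if (params$circular) {
    # rolling means over wrapped windows: rmc[i] = mean over w positions
    # starting at i, indices modulo L
    rmc <- rollMean(c(v, v[seq_len(w - 1L)]), w)
    wrap <- function(i) ((i - 1L) %% L) + 1L
    idx <- seq_len(L)
    startFold <- (rmc[idx] + eps) / (rmc[wrap(idx - s - w)] + eps)
    startOK <- rep(TRUE, L)
    endFold <- (rmc[wrap(idx - w + 1L)] + eps) / (rmc[wrap(idx + s + 1L)] + eps)
    endOK <- rep(TRUE, L)
    startPos <- endPos <- idx
  } else {
    rm <- rollMean(v, w) # rm[i] = mean(v[i..i+w-1]), i in 1..L-w+1
    startPos <- seq.int(s + w + 1L, L - w + 1L)
    startFold <- (rm[startPos] + eps) / (rm[startPos - s - w] + eps)
    startOK <- rep(TRUE, length(startPos))
    endPos <- seq.int(w, L - s - w)
    endFold <- (rm[endPos - w + 1L] + eps) / (rm[endPos + s + 1L] + eps)
    endOK <- rep(TRUE, length(endPos))
  }

  starts <- collapseRuns(startPos[startOK & startFold >= params$fold],
    startFold[startOK & startFold >= params$fold],
    tie = "left"
  )
  ends <- collapseRuns(endPos[endOK & endFold >= params$fold],
    endFold[endOK & endFold >= params$fold],
    tie = "right"
  )
  out <- rbind(
    data.frame(
      position = starts$position, kind = rep("start", nrow(starts)),
      fold = starts$fold
    ),
    data.frame(
      position = ends$position, kind = rep("end", nrow(ends)),
      fold = ends$fold
    )
  )
  out <- out[order(out$position, match(out$kind, c("start", "end"))), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

# collapse maximal runs of consecutive positions to the position of
# maximal fold; ties broken to the left or right end of the tied set
collapseRuns <- function(positions, folds, tie = c("left", "right")) {
  tie <- match.arg(tie)
  if (!length(positions)) {
    return(data.frame(position = integer(0), fold = numeric(0)))
  }
  runId <- cumsum(c(1L, diff(positions) != 1L))
  keep <- vapply(split(seq_along(positions), runId), function(ix) {
    f <- folds[ix]
    best <- which(f == max(f))
    ix[if (tie == "left") best[1L] else best[length(best)]]
  }, integer(1))
  data.frame(position = positions[keep], fold = folds[keep])
}

#' Pair boundary candidates into peak intervals
#'
#' Left-to-right scan over position-sorted candidates: the first start
#' opens an interval; further starts before an end are interior and
#' ignored; the first end at a position >= the opening start closes the
#' interval. Ends with no open interval are ignored. An interval still
#' open when the scan terminates is closed at `trackLength` if
#' `closeOpenPeaks`, else discarded. Intervals shorter than `minPeakLen`
#' are discarded.
#'
#' @param candidates a boundary `data.frame` from [scanBoundaries()].
#' @param trackLength track length in nt.
#' @param params a [peakCallParams()] list.
#' @return An [IRanges::IRanges] of peak intervals (1-based inclusive).
#' @export
pairBoundaries <- function(candidates, trackLength,
                           params = peakCallParams()) {
  params <- asPeakCallParams(params)
  startsV <- integer(0)
  endsV <- integer(0)
  open <- NA_integer_
  if (nrow(candidates)) {
    ord <- order(candidates$position, match(candidates$kind, c("start", "end")))
    candidates <- candidates[ord, , drop = FALSE]
    for (k in seq_len(nrow(candidates))) {
      pos <- candidates$position[k]
      if (candidates$kind[k] == "start") {
        if (is.na(open)) open <- pos
      } else if (!is.na(open) && pos >= open) {
        startsV <- c(startsV, open)
        endsV <- c(endsV, pos)
        open <- NA_integer_
      }
    }
  }
  if (!is.na(open) && params$closeOpenPeaks) {
    startsV <- c(startsV, open)
    endsV <- c(endsV, as.integer(trackLength))
  }
  ir <- IRanges::IRanges(start = startsV, end = endsV)
  ir[BiocGenerics::width(ir) >= params$minPeakLen]
}

#' Dataset-wide mean coverage per nucleotide
#'
#' Grand mean over all positions of all supplied tracks — by default both
#' strands of the library being peak-called. This is the reference for
#' the relative coverage filter in [callPeaks()].
#'
#' @param tracks non-empty list of [CoverageTrack-class] objects of equal
#'   length.
#' @return A single non-negative number.
#' @export
datasetMeanCoverage <- function(tracks) {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  if (!length(tracks)) stopDomain("empty track list")
  len <- vapply(tracks, trackLength, integer(1))
  if (length(unique(len)) != 1L) {
    stopIncompatible("tracks differ in length")
  }
  tot <- sum(vapply(tracks, function(t) sum(coverageValues(t)), numeric(1)))
  tot / sum(len)
}

#' Call coverage peaks on one strand
#'
#' Runs [scanBoundaries()] and [pairBoundaries()], then keeps intervals
#' whose mean coverage reaches `minCovFrac` of the dataset mean (computed
#' over `track` plus `companionTracks`, normally the library's other
#' strand). Both the boundary test and the coverage filter are ratios, so
#' peak calls are invariant to any common rescaling of the coverage (with
#' the pseudocount co-scaled).
#'
#' @param track the [CoverageTrack-class] to call peaks on (typically the
#'   positionwise mean of the normalized pull-down replicates).
#' @param companionTracks list of tracks completing the dataset for the
#'   coverage filter; may be empty, then the dataset is `track` alone.
#' @param params a [peakCallParams()] list.
#' @param firstId peak id assigned to the first peak; ids continue in
#'   coordinate order (the genome-wide convention numbers forward-strand
#'   peaks first, then continues on the reverse strand).
#' @return A [GenomicRanges::GRanges] with metadata columns `peak_id`,
#'   `mean_coverage` and `source_label`; per strand the peaks are disjoint
#'   and sorted by start.
#' @examples
#' v <- c(rep(10, 50), rep(20, 70), rep(10, 80))
#' tr <- CoverageTrack(v, "F", label = "demo", normalized = TRUE)
#' callPeaks(tr) # one peak, 51..120
#' @export
callPeaks <- function(track, companionTracks = list(),
                      params = peakCallParams(), firstId = 1L) {
  stopifnot(is(track, "CoverageTrack"))
  params <- asPeakCallParams(params)
  cands <- scanBoundaries(track, params)
  ir <- pairBoundaries(cands, trackLength(track), params)
  dsMean <- datasetMeanCoverage(c(list(track), companionTracks))
  v <- coverageValues(track)
  if (length(ir)) {
    meanCov <- vapply(seq_along(ir), function(k) {
      mean(v[BiocGenerics::start(ir)[k]:BiocGenerics::end(ir)[k]])
    }, numeric(1))
    keep <- meanCov >= params$minCovFrac * dsMean
    ir <- ir[keep]
    meanCov <- meanCov[keep]
  } else {
    meanCov <- numeric(0)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genomeId(track), length(ir)), ranges = ir,
    strand = rep(strand(track), length(ir)),
    seqinfo = GenomeInfoDb::Seqinfo(
      seqnames = genomeId(track), seqlengths = trackLength(track)
    )
  )
  S4Vectors::mcols(gr)$peak_id <- seq_along(gr) + as.integer(firstId) - 1L
  S4Vectors::mcols(gr)$mean_coverage <- meanCov
  S4Vectors::mcols(gr)$source_label <- rep(trackLabel(track), length(gr))
  gr
}

#' Call peaks on both strands with genome-wide peak ids
#'
#' Convenience wrapper: calls peaks on the forward track, then on the
#' reverse track with continuing ids; the dataset mean for the coverage
#' filter pools both strands.
#'
#' @param fwd,rev forward / reverse [CoverageTrack-class] of one library.
#' @param params a [peakCallParams()] list.
#' @return A [GenomicRanges::GRanges] with forward peaks first.
#' @export
callPeaksBothStrands <- function(fwd, rev, params = peakCallParams()) {
  pf <- callPeaks(fwd, list(rev), params, firstId = 1L)
  pr <- callPeaks(rev, list(fwd), params, firstId = length(pf) + 1L)
  suppressWarnings(c(pf, pr))
}
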