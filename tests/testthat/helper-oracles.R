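# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops and first-principles formulas, sharing no
# code with the package implementation.

# --- peak calling ---------------------------------------------------------

bfWindowMean <- function(v, from, to) {
  if (from < 1 || to > length(v)) return(NA_real_)
  s <- 0
  for (p in from:to) s <- s + v[p]
  s / (to - from + 1)
}

# every position evaluated one by one; runs collapsed by explicit walk
bfScanBoundaries <- function(v, w, s, f, eps) {
  L <- length(v)
  starts <- list()
  ends <- list()
  for (i in seq_len(L)) {
    hi <- bfWindowMean(v, i, i + w - 1)
    up <- bfWindowMean(v, i - s - w, i - s - 1)
    if (!is.na(hi) && !is.na(up) && (hi + eps) / (up + eps) >= f) {
      starts[[length(starts) + 1]] <- c(i, (hi + eps) / (up + eps))
    }
    hi2 <- bfWindowMean(v, i - w + 1, i)
    dn <- bfWindowMean(v, i + s + 1, i + s + w)
    if (!is.na(hi2) && !is.na(dn) && (hi2 + eps) / (dn + eps) >= f) {
      ends[[length(ends) + 1]] <- c(i, (hi2 + eps) / (dn + eps))
    }
  }
  collapse <- function(cand, rightTie) {
    if (!length(cand)) {
      return(data.frame(position = integer(0), fold = numeric(0)))
    }
    pos <- vapply(cand, `[`, numeric(1), 1)
    fold <- vapply(cand, `[`, numeric(1), 2)
    out <- list()
    runStart <- 1
    for (k in seq_along(pos)) {
      endOfRun <- k == length(pos) || pos[k + 1] != pos[k] + 1
      if (endOfRun) {
        ix <- runStart:k
        best <- ix[fold[ix] == max(fold[ix])]
        pick <- if (rightTie) best[length(best)] else best[1]
        out[[length(out) + 1]] <- c(pos[pick], fold[pick])
        runStart <- k + 1
      }
    }
    data.frame(
      position = vapply(out, `[`, numeric(1), 1),
      fold = vapply(out, `[`, numeric(1), 2)
    )
  }
  list(starts = collapse(starts, FALSE), ends = collapse(ends, TRUE))
}

bfPairBoundaries <- function(startPos, endPos, trackLength, minLen = 1,
                             closeOpen = FALSE) {
  events <- rbind(
    if (length(startPos)) data.frame(pos = startPos, kind = "start"),
    if (length(endPos)) data.frame(pos = endPos, kind = "end")
  )
  out <- NULL
  open <- NA
  if (!is.null(events)) {
    events <- events[order(events$pos, events$kind != "start"), ]
    for (k in seq_len(nrow(events))) {
      if (events$kind[k] == "start") {
        if (is.na(open)) open <- events$pos[k]
      } else if (!is.na(open) && events$pos[k] >= open) {
        out <- rbind(out, c(open, events$pos[k]))
        open <- NA
      }
    }
  }
  if (!is.na(open) && closeOpen) out <- rbind(out, c(open, trackLength))
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  out[out[, 2] - out[, 1] + 1 >= minLen, , drop = FALSE]
}

# end-to-end naive caller: scan, pair, 20% dataset-mean filter
bfCallPeaks <- function(v, companions = list(), w = 5, s = 10, f = 1.5,
                        c_ = 0.2, eps = 0.1, minLen = 1,
                        closeOpen = FALSE) {
  if (length(v) < 2 * w + s) {
    b <- list(
      starts = data.frame(position = integer(0)),
      ends = data.frame(position = integer(0))
    )
  } else {
    b <- bfScanBoundaries(v, w, s, f, eps)
  }
  iv <- bfPairBoundaries(
    b$starts$position, b$ends$position, length(v), minLen, closeOpen
  )
  all <- c(v, unlist(companions))
  dsMean <- sum(all) / length(all)
  keep <- logical(nrow(iv))
  mc <- numeric(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    mc[k] <- bfWindowMean(v, iv[k, 1], iv[k, 2])
    keep[k] <- mc[k] >= c_ * dsMean
  }
  cbind(iv[keep, , drop = FALSE], mc[keep])
}

# random piecewise-constant track with noise: produces realistic runs of
# boundary candidates and near-threshold folds
randomTrack <- function(len, maxSegs = 8) {
  nseg <- sample(seq_len(maxSegs), 1)
  bounds <- sort(sample(len, nseg - 1))
  levels_ <- stats::runif(nseg, 0, 40)
  v <- rep(levels_, diff(c(0, bounds, len)))
  pmax(0, v + stats::rnorm(len, 0, 0.5))
}

# --- annotation -----------------------------------------------------------

# features: data.frame(feature_id, kind, strand, start, end)
bfClassifyPeak <- function(pStart, pEnd, pStrand, features) {
  best <- NULL
  for (i in seq_len(nrow(features))) {
    ov <- min(pEnd, features$end[i]) - max(pStart, features$start[i]) + 1
    if (ov <= 0) next
    prec <- match(
      features$kind[i],
      c("five_prime_UTR", "three_prime_UTR", "RNA_gene", "CDS")
    )
    width <- features$end[i] - features$start[i] + 1
    key <- list(
      ov = ov, prec = prec, width = width, id = features$feature_id[i],
      i = i
    )
    if (is.null(best)) {
      best <- key
    } else {
      better <- (key$ov > best$ov) ||
        (key$ov == best$ov && key$prec < best$prec) ||
        (key$ov == best$ov && key$prec == best$prec &&
           key$width < best$width) ||
        (key$ov == best$ov && key$prec == best$prec &&
           key$width == best$width && key$id < best$id)
      if (better) best <- key
    }
  }
  if (is.null(best)) return("intergenic")
  kindCat <- c(
    CDS = "CDS", RNA_gene = "RNA",
    five_prime_UTR = "5UTR", three_prime_UTR = "3UTR"
  )[[features$kind[best$i]]]
  if (features$strand[best$i] != pStrand) kindCat <- paste0("as", kindCat)
  kindCat
}

featuresToGRanges <- function(features, genomeLength = 10000) {
  fs <- GenomicRanges::GRanges(
    seqnames = rep("genome", nrow(features)),
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand,
    seqlengths = c(genome = genomeLength)
  )
  S4Vectors::mcols(fs) <- S4Vectors::DataFrame(
    feature_id = features$feature_id,
    gene_name = features$feature_id,
    kind = features$kind,
    parent_id = features$feature_id,
    functional_category = rep(NA_character_, nrow(features))
  )
  fs
}

# --- statistics -----------------------------------------------------------

# exact upper-tail probability by enumerating every possible target draw
bfHypergeomTail <- function(nBackground, kInCat, nTargets, kObserved) {
  draws <- utils::combn(nBackground, nTargets)
  inCat <- seq_len(kInCat) # which background items are category members
  hits <- apply(draws, 2, function(d) sum(d %in% inCat))
  mean(hits >= kObserved)
}

# H from first principles (rank sums, tie correction), no shared code
bfKwH <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (g in seq_along(groups)) {
    Rg <- sum(r[idx == g])
    H <- H + Rg^2 / sum(idx == g)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- table(x)
  denom <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (denom == 0) 0 else H / denom
}

# exact two-group permutation distribution of H via combn
bfKwPermutationP <- function(g1, g2) {
  x <- c(g1, g2)
  n1 <- length(g1)
  Hobs <- bfKwH(list(g1, g2))
  picks <- utils::combn(length(x), n1)
  Hs <- apply(picks, 2, function(ix) bfKwH(list(x[ix], x[-ix])))
  mean(Hs >= Hobs - 1e-12)
}

# --- misc -----------------------------------------------------------------

normPair <- function(lib) {
  list(
    fwd = normalizeToLibrarySize(lib$fwd, companions = list(lib$rev)),
    rev = normalizeToLibrarySize(lib$rev, companions = list(lib$fwd))
  )
}

# run the full synthetic pipeline (normalize, merge, call, classify)
runSyntheticPipeline <- function(cfg) {
  fs <- simulateAnnotation(cfg)
  sim <- simulateLibraries(cfg, fs)
  reps <- lapply(sim$pulldown, normPair)
  ctrl <- normPair(sim$control)
  merged <- list(
    fwd = mergeTracks(lapply(reps, `[[`, "fwd")),
    rev = mergeTracks(lapply(reps, `[[`, "rev"))
  )
  peaks <- callPeaksBothStrands(merged$fwd, merged$rev)
  calls <- suppressWarnings(do.call(c, lapply(c("+", "-"), function(sd) {
    sel <- as.character(BiocGenerics::strand(peaks)) == sd
    side <- if (sd == "+") "fwd" else "rev"
    classifyPeaks(peaks[sel], lapply(reps, `[[`, side), ctrl[[side]])
  })))
  list(fs = fs, sim = sim, merged = merged, calls = calls)
}
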