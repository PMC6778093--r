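#' Simulation settings for synthetic pull-down libraries
#'
#' Defines the synthetic study conditions: a single bacterial-scale
#' replicon with non-overlapping genes per strand (opposite-strand
#' overlap is allowed, as in dense bacterial genomes), a flat noisy
#' background shared between pull-down and control, planted
#' multiplicative enrichment peaks, sub-threshold decoy peaks, duplicate
#' pull-down libraries with different sequencing depths, and an
#' unenriched control.
#'
#' @param genomeLength replicon length in nt.
#' @param nGenes number of genes.
#' @param geneLengthRange min/max gene body length in nt.
#' @param rnaGeneFrac fraction of genes emitted as RNA genes (no UTRs).
#' @param backgroundMean background coverage mean per nucleotide.
#' @param noiseModel `"poisson"`, `"negbin"` or `"delta"` (no noise: the
#'   tracks equal their expected coverage exactly).
#' @param nbDispersion negative-binomial size parameter (overdispersion;
#'   used only when `noiseModel = "negbin"`).
#' @param nTruePeaks number of planted enriched peaks.
#' @param trueFoldRange min/max multiplicative fold of true peaks.
#' @param nDecoyPeaks number of planted sub-threshold decoy peaks.
#' @param decoyFoldRange min/max multiplicative fold of decoys.
#' @param peakWidthRange min/max planted peak width in nt.
#' @param replicateJitterSd sd of the per-peak, per-replicate lognormal
#'   jitter on the planted fold (log scale).
#' @param nReplicates number of pull-down replicate libraries.
#' @param depthFactors per-replicate sequencing-depth multipliers on the
#'   raw counts (recycled); unequal depths exercise normalization.
#' @param seed integer seed; the whole simulation is reproducible from
#'   it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(genomeLength = 50000L, nGenes = 60L,
                             geneLengthRange = c(200L, 1500L),
                             rnaGeneFrac = 0.15,
                             backgroundMean = 25,
                             noiseModel = c("poisson", "negbin", "delta"),
                             nbDispersion = 10,
                             nTruePeaks = 30L,
                             trueFoldRange = c(2.5, 6.0),
                             nDecoyPeaks = 10L,
                             decoyFoldRange = c(1.0, 1.4),
                             peakWidthRange = c(30L, 150L),
                             replicateJitterSd = 0.1,
                             nReplicates = 2L,
                             depthFactors = c(1, 1.6),
                             seed = 42L) {
  noiseModel <- match.arg(noiseModel)
  rangeOK <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
  if (!rangeOK(geneLengthRange) || !rangeOK(trueFoldRange) ||
      !rangeOK(decoyFoldRange) || !rangeOK(peakWidthRange)) {
    stopDomain("ranges must be positive and ordered")
  }
  if (backgroundMean <= 0) stopDomain("'backgroundMean' must be positive")
  if (nReplicates < 1L) stopDomain("need at least one replicate")
  structure(
    list(
      genomeLength = as.integer(genomeLength), nGenes = as.integer(nGenes),
      geneLengthRange = as.integer(geneLengthRange),
      rnaGeneFrac = rnaGeneFrac,
      backgroundMean = backgroundMean, noiseModel = noiseModel,
      nbDispersion = nbDispersion,
      nTruePeaks = as.integer(nTruePeaks), trueFoldRange = trueFoldRange,
      nDecoyPeaks = as.integer(nDecoyPeaks),
      decoyFoldRange = decoyFoldRange,
      peakWidthRange = as.integer(peakWidthRange),
      replicateJitterSd = replicateJitterSd,
      nReplicates = as.integer(nReplicates),
      depthFactors = rep_len(depthFactors, nReplicates),
      seed = as.integer(seed)
    ),
    class = "SimulationConfig"
  )
}

simGenomeId <- "simgenome"
simFlank5 <- 100L
simFlank3 <- 50L
simMinGap <- 50L

#' Simulate a genome annotation
#'
#' Places `nGenes` genes with random strands and lengths so that genes
#' (including their UTR flanks) never overlap on the same strand and
#' keep at least 50 nt same-strand gaps. CDS genes carry explicit 100 nt
#' 5'UTR and 50 nt 3'UTR records; a fraction are RNA genes without UTRs.
#' Each gene is assigned one of ten functional categories. The output is
#' byte-deterministic for a given config.
#'
#' @param cfg a [simulationConfig()].
#' @param gffPath optional path; when given, the annotation is written
#'   there as GFF3.
#' @return A feature-set `GRanges` (as from [readGff()]), with the GFF3
#'   path in `metadata(fs)$gffPath` when written.
#' @export
simulateAnnotation <- function(cfg = simulationConfig(), gffPath = NULL) {
  set.seed(cfg$seed)
  n <- cfg$nGenes
  cats <- c(
    "translation", "photosynthesis and respiration", "energy metabolism",
    "regulatory functions", "transport and binding",
    "cell envelope", "amino acid biosynthesis",
    "biosynthesis of cofactors", "DNA replication and repair",
    "hypothetical"
  )
  rows <- list()
  if (n > 0L) {
    strands <- sample(c("+", "-"), n, replace = TRUE)
    lens <- sample(
      seq.int(cfg$geneLengthRange[1], cfg$geneLengthRange[2]), n,
      replace = TRUE
    )
    isRna <- stats::runif(n) < cfg$rnaGeneFrac
    category <- sample(cats, n, replace = TRUE)
    for (sd in c("+", "-")) {
      ix <- which(strands == sd)
      if (!length(ix)) next
      fp <- ifelse(isRna[ix], lens[ix], lens[ix] + simFlank5 + simFlank3)
      need <- sum(fp) + simMinGap * (length(ix) + 1L)
      if (need > cfg$genomeLength) {
        stopDomain(
          "cannot place ", length(ix), " genes on strand ", sd,
          " in ", cfg$genomeLength, " nt; reduce 'nGenes'"
        )
      }
      slack <- cfg$genomeLength - need
      u <- stats::runif(length(ix) + 1L)
      extra <- floor(slack * u / sum(u))
      cursor <- 1L
      for (k in seq_along(ix)) {
        i <- ix[k]
        cursor <- cursor + simMinGap + extra[k]
        fpStart <- cursor
        if (isRna[i]) {
          rows[[length(rows) + 1L]] <- data.frame(
            id = sprintf("gene%03d", i), kind = "RNA_gene", strand = sd,
            start = fpStart, end = fpStart + lens[i] - 1L,
            parent = sprintf("gene%03d", i), category = category[i]
          )
          cursor <- fpStart + lens[i]
        } else {
          gid <- sprintf("gene%03d", i)
          if (sd == "+") {
            u5 <- c(fpStart, fpStart + simFlank5 - 1L)
            cds <- c(u5[2] + 1L, u5[2] + lens[i])
            u3 <- c(cds[2] + 1L, cds[2] + simFlank3)
          } else {
            u3 <- c(fpStart, fpStart + simFlank3 - 1L)
            cds <- c(u3[2] + 1L, u3[2] + lens[i])
            u5 <- c(cds[2] + 1L, cds[2] + simFlank5)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            id = gid, kind = "CDS", strand = sd,
            start = cds[1], end = cds[2], parent = gid,
            category = category[i]
          )
          rows[[length(rows) + 1L]] <- data.frame(
            id = paste0(gid, ".5utr"), kind = "five_prime_UTR", strand = sd,
            start = u5[1], end = u5[2], parent = gid, category = category[i]
          )
          rows[[length(rows) + 1L]] <- data.frame(
            id = paste0(gid, ".3utr"), kind = "three_prime_UTR", strand = sd,
            start = u3[1], end = u3[2], parent = gid, category = category[i]
          )
          cursor <- fpStart + lens[i] + simFlank5 + simFlank3
        }
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(
      id = character(0), kind = character(0), strand = character(0),
      start = integer(0), end = integer(0), parent = character(0),
      category = character(0)
    )
  fs <- GenomicRanges::GRanges(
    seqnames = rep(simGenomeId, nrow(tab)),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand,
    seqlengths = stats::setNames(cfg$genomeLength, simGenomeId)
  )
  S4Vectors::mcols(fs) <- S4Vectors::DataFrame(
    feature_id = tab$id, gene_name = tab$id, kind = tab$kind,
    parent_id = tab$parent, functional_category = tab$category
  )
  fs <- BiocGenerics::sort(fs, ignore.strand = TRUE)
  if (!is.null(gffPath)) {
    writeFeatureGff(fs, gffPath)
    S4Vectors::metadata(fs)$gffPath <- gffPath
  }
  fs
}

kindToGffType <- c(
  CDS = "CDS", RNA_gene = "ncRNA",
  five_prime_UTR = "five_prime_UTR", three_prime_UTR = "three_prime_UTR"
)

# canonical, byte-deterministic GFF3 writer for simulated feature sets
writeFeatureGff <- function(fs, path) {
  mc <- S4Vectors::mcols(fs)
  lines <- c(
    "##gff-version 3",
    sprintf(
      "##sequence-region %s 1 %d",
      GenomeInfoDb::seqlevels(fs)[1L],
      GenomeInfoDb::seqlengths(fs)[1L]
    )
  )
  if (length(fs)) {
    attrs <- sprintf(
      "ID=%s;Name=%s;category=%s", mc$feature_id, mc$gene_name,
      mc$functional_category
    )
    child <- mc$parent_id != mc$feature_id
    attrs[child] <- paste0(attrs[child], ";Parent=", mc$parent_id[child])
    lines <- c(lines, sprintf(
      "%s\tcrafdseq_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
      as.character(GenomeInfoDb::seqnames(fs)),
      kindToGffType[mc$kind],
      BiocGenerics::start(fs), BiocGenerics::end(fs),
      as.character(BiocGenerics::strand(fs)), attrs
    ))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Simulate pull-down and control coverage libraries with ground truth
#'
#' The expected coverage is a flat background shared by every library.
#' Planted peaks multiply the pull-down expectation over their interval
#' by their fold (true peaks at an enriched fold, decoys below the
#' enrichment threshold); the control carries no planted signal.
#' Replicates additionally get a per-peak lognormal fold jitter and a
#' global depth factor, and every track is re-sampled under the noise
#' model, so raw totals differ between libraries and library-size
#' normalization is exercised. Planted peaks are placed to overlap a
#' random annotated feature, on a random strand, disjoint per strand.
#'
#' @param cfg a [simulationConfig()].
#' @param fs the feature set from [simulateAnnotation()] (same config).
#' @return A list: `pulldown` (list per replicate of
#'   `list(fwd =, rev =)` raw [CoverageTrack-class]s), `control`
#'   (`list(fwd =, rev =)`), and `truth`, a `data.frame` with columns
#'   `truth_id`, `is_true`, `strand`, `start`, `end`, `true_fold`,
#'   `overlapped_feature` and `expected_category` (the latter computed
#'   with [annotatePeaks()]).
#' @export
simulateLibraries <- function(cfg = simulationConfig(),
                              fs = simulateAnnotation(cfg)) {
  set.seed(cfg$seed + 1L)
  L <- cfg$genomeLength
  minSep <- 60L # keeps boundary windows of neighbouring peaks independent

  placed <- list(`+` = cbind(integer(0), integer(0)),
                 `-` = cbind(integer(0), integer(0)))
  placePeak <- function(width) {
    for (try in seq_len(2000L)) {
      sd <- sample(c("+", "-"), 1L)
      if (length(fs)) {
        fi <- sample(length(fs), 1L)
        fst <- BiocGenerics::start(fs)[fi]
        fen <- BiocGenerics::end(fs)[fi]
        feat <- S4Vectors::mcols(fs)$feature_id[fi]
        lo <- max(1L, fst - width + 10L)
        hi <- min(L - width + 1L, fen - 9L)
      } else {
        feat <- NA_character_
        lo <- 1L
        hi <- L - width + 1L
      }
      if (lo > hi) next
      st <- sample(seq.int(lo, hi), 1L)
      en <- st + width - 1L
      others <- placed[[sd]]
      if (nrow(others) &&
          any(st <= others[, 2] + minSep & en >= others[, 1] - minSep)) {
        next
      }
      placed[[sd]] <<- rbind(others, c(st, en))
      return(list(strand = sd, start = st, end = en, feature = feat))
    }
    stopDomain("could not place a planted peak; reduce peak count or width")
  }

  nT <- cfg$nTruePeaks
  nD <- cfg$nDecoyPeaks
  widths <- sample(
    seq.int(cfg$peakWidthRange[1], cfg$peakWidthRange[2]), nT + nD,
    replace = TRUE
  )
  folds <- c(
    stats::runif(nT, cfg$trueFoldRange[1], cfg$trueFoldRange[2]),
    stats::runif(nD, cfg$decoyFoldRange[1], cfg$decoyFoldRange[2])
  )
  spots <- lapply(widths, placePeak)
  truth <- data.frame(
    truth_id = c(
      sprintf("T%03d", seq_len(nT)),
      if (nD) sprintf("D%03d", seq_len(nD)) else character(0)
    ),
    is_true = rep(c(TRUE, FALSE), c(nT, nD)),
    strand = vapply(spots, function(s) s$strand, character(1)),
    start = vapply(spots, function(s) s$start, integer(1)),
    end = vapply(spots, function(s) s$end, integer(1)),
    true_fold = folds,
    overlapped_feature = vapply(spots, function(s) s$feature, character(1)),
    stringsAsFactors = FALSE
  )

  # per-peak, per-replicate lognormal jitter on the planted fold
  jitter <- matrix(
    exp(stats::rnorm((nT + nD) * cfg$nReplicates, 0, cfg$replicateJitterSd)),
    nrow = nT + nD, ncol = cfg$nReplicates
  )

  drawNoise <- function(mu) {
    switch(cfg$noiseModel,
      poisson = stats::rpois(length(mu), mu),
      negbin = stats::rnbinom(length(mu), mu = mu, size = cfg$nbDispersion),
      delta = mu
    )
  }
  foldVec <- function(rep) {
    out <- list(`+` = rep(1, L), `-` = rep(1, L))
    for (k in seq_len(nrow(truth))) {
      f <- truth$true_fold[k] * (if (is.null(rep)) 1 else jitter[k, rep])
      sd <- truth$strand[k]
      out[[sd]][truth$start[k]:truth$end[k]] <-
        out[[sd]][truth$start[k]:truth$end[k]] * f
    }
    out
  }
  mkTrack <- function(values, strand, label) {
    CoverageTrack(values, strand,
      genomeId = simGenomeId, label = label, normalized = FALSE
    )
  }

  control <- list(
    fwd = mkTrack(drawNoise(rep(cfg$backgroundMean, L)), "+", "control"),
    rev = mkTrack(drawNoise(rep(cfg$backgroundMean, L)), "-", "control")
  )
  pulldown <- lapply(seq_len(cfg$nReplicates), function(r) {
    fv <- foldVec(r)
    d <- cfg$depthFactors[r]
    lab <- sprintf("pulldown_rep%d", r)
    list(
      fwd = mkTrack(drawNoise(cfg$backgroundMean * d * fv[["+"]]), "+", lab),
      rev = mkTrack(drawNoise(cfg$backgroundMean * d * fv[["-"]]), "-", lab)
    )
  })
  names(pulldown) <- sprintf("rep%d", seq_len(cfg$nReplicates))

  if (nrow(truth)) {
    tg <- GenomicRanges::GRanges(
      seqnames = rep(simGenomeId, nrow(truth)),
      ranges = IRanges::IRanges(start = truth$start, end = truth$end),
      strand = truth$strand
    )
    S4Vectors::mcols(tg)$peak_id <- seq_len(nrow(truth))
    truth$expected_category <-
      S4Vectors::mcols(annotatePeaks(tg, fs))$category
  } else {
    truth$expected_category <- character(0)
  }

  list(pulldown = pulldown, control = control, truth = truth)
}

#' Score recovery of planted peaks
#'
#' Matches enriched calls to planted truth intervals by same-strand
#' reciprocal overlap of at least 50%, and reports recall over the true
#' planted peaks, precision of the enriched calls, boundary-error
#' quantiles over matched pairs, and the number of decoys called
#' enriched.
#'
#' @param calls a peak `GRanges`; when a `status` column is present (see
#'   [classifyPeaks()]) only `enriched` peaks are scored, otherwise all.
#' @param truth the truth `data.frame` from [simulateLibraries()].
#' @param toleranceNt boundary tolerance used for the
#'   `frac_within_tolerance` summary (default 15 nt).
#' @return A list of class `RecoveryReport`: `recall`, `precision`,
#'   `no_calls` (flag: precision is 1 by convention when nothing was
#'   called), `n_called`, `n_matched`, `boundary_errors`,
#'   `median_boundary_error`, `frac_within_tolerance`,
#'   `n_decoys_enriched`.
#' @export
scoreRecovery <- function(calls, truth, toleranceNt = 15L) {
  mc <- S4Vectors::mcols(calls)
  if (!is.null(mc$status)) {
    calls <- calls[mc$status == "enriched"]
  }
  cs <- BiocGenerics::start(calls)
  ce <- BiocGenerics::end(calls)
  cstr <- as.character(BiocGenerics::strand(calls))
  recip <- function(ti, ci) {
    ov <- min(truth$end[ti], ce[ci]) - max(truth$start[ti], cs[ci]) + 1L
    if (ov <= 0L || truth$strand[ti] != cstr[ci]) return(FALSE)
    ov >= 0.5 * (truth$end[ti] - truth$start[ti] + 1L) &&
      ov >= 0.5 * (ce[ci] - cs[ci] + 1L)
  }
  nC <- length(calls)
  matchOf <- rep(NA_integer_, nrow(truth))
  callMatched <- rep(FALSE, nC)
  for (ti in seq_len(nrow(truth))) {
    for (ci in seq_len(nC)) {
      if (recip(ti, ci)) {
        matchOf[ti] <- ci
        callMatched[ci] <- TRUE
        break
      }
    }
  }
  isTrue <- truth$is_true
  nTrue <- sum(isTrue)
  recall <- if (nTrue) sum(!is.na(matchOf[isTrue])) / nTrue else NA_real_
  # precision counts calls explained by any planted signal (true peaks)
  matchedTrueCalls <- unique(stats::na.omit(matchOf[isTrue]))
  noCalls <- nC == 0L
  precision <- if (noCalls) 1.0 else length(matchedTrueCalls) / nC
  be <- integer(0)
  for (ti in which(isTrue & !is.na(matchOf))) {
    ci <- matchOf[ti]
    be <- c(be, abs(cs[ci] - truth$start[ti]), abs(ce[ci] - truth$end[ti]))
  }
  structure(
    list(
      recall = recall, precision = precision, no_calls = noCalls,
      n_called = nC, n_matched = sum(!is.na(matchOf[isTrue])),
      boundary_errors = be,
      median_boundary_error = if (length(be)) stats::median(be) else NA_real_,
      frac_within_tolerance = if (length(be)) mean(be <= toleranceNt)
        else NA_real_,
      n_decoys_enriched = sum(!isTrue & !is.na(matchOf))
    ),
    class = "RecoveryReport"
  )
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Recovery of planted peaks: recall %.3f, precision %.3f",
      " (%d calls, %d matched)\n",
      "  median boundary error %s nt; decoys called enriched: %d%s\n"
    ),
    x$recall, x$precision, x$n_called, x$n_matched,
    format(x$median_boundary_error), x$n_decoys_enriched,
    if (x$no_calls) " [no calls: precision 1 by convention]" else ""
  ))
  invisible(x)
}
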