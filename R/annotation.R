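featureKinds <- c("CDS", "RNA_gene", "five_prime_UTR", "three_prime_UTR")

kindToCategory <- c(
  CDS = "CDS", RNA_gene = "RNA",
  five_prime_UTR = "5UTR", three_prime_UTR = "3UTR"
)

#' The peak category vocabulary
#'
#' Eight genomic categories — sense and antisense versions of CDS, 5'UTR,
#' 3'UTR and RNA gene — plus `intergenic` for peaks overlapping no
#' feature.
#' @return Character vector of the nine category labels.
#' @export
peakCategories <- function() {
  c(
    "CDS", "5UTR", "3UTR", "RNA",
    "asCDS", "as5UTR", "as3UTR", "asRNA", "intergenic"
  )
}

gffTypeToKind <- function(type) {
  type <- as.character(type)
  out <- rep(NA_character_, length(type))
  out[type == "CDS"] <- "CDS"
  out[type %in% c(
    "ncRNA", "tRNA", "rRNA", "sRNA", "antisense_RNA", "tmRNA", "SRP_RNA",
    "RNase_P_RNA"
  )] <- "RNA_gene"
  out[type == "five_prime_UTR"] <- "five_prime_UTR"
  out[type == "three_prime_UTR"] <- "three_prime_UTR"
  out
}

#' Read genome features from GFF3
#'
#' Imports CDS, RNA-gene (`ncRNA`, `tRNA`, `rRNA`, ...) and optional
#' `five_prime_UTR`/`three_prime_UTR` records into a feature set: a
#' [GenomicRanges::GRanges] with metadata columns `feature_id`,
#' `gene_name`, `kind`, `parent_id` and `functional_category`. `gene`
#' records are not features themselves; their `Name` and category
#' attribute are inherited by their child records. Records of any other
#' type are skipped with a message reporting the count.
#'
#' @param path GFF3 file.
#' @param genomeLength replicon length; features extending beyond it are
#'   an error.
#' @param categoryAttr attribute key carrying the functional category
#'   (default `"category"`).
#' @return A `GRanges` feature set with `seqlengths` set to
#'   `genomeLength`.
#' @export
readGff <- function(path, genomeLength, categoryAttr = "category") {
  if (!file.exists(path)) stopIO("GFF3 file not found: ", path)
  genomeLength <- as.integer(genomeLength)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  kind <- gffTypeToKind(mc$type)
  isGene <- as.character(mc$type) == "gene"
  nSkipped <- sum(is.na(kind) & !isGene)
  if (nSkipped > 0) {
    message("readGff: skipped ", nSkipped, " record(s) of unhandled type")
  }

  getAttr <- function(mc, key) {
    if (key %in% colnames(mc)) as.character(mc[[key]]) else
      rep(NA_character_, nrow(mc))
  }
  firstParent <- function(p) {
    if (is.null(p)) return(rep(NA_character_, length(gr)))
    vapply(as.list(p), function(x) {
      if (length(x)) as.character(x)[1L] else NA_character_
    }, character(1))
  }

  ids <- getAttr(mc, "ID")
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("feature", which(is.na(ids)))
  names_ <- getAttr(mc, "Name")
  cats <- getAttr(mc, categoryAttr)
  parents <- firstParent(mc$Parent)

  # inherit name/category from gene containers
  if (any(isGene)) {
    geneName <- stats::setNames(names_[isGene], ids[isGene])
    geneCat <- stats::setNames(cats[isGene], ids[isGene])
    fromGene <- !is.na(parents) & parents %in% ids[isGene]
    fill <- fromGene & is.na(names_)
    names_[fill] <- geneName[parents[fill]]
    fill <- fromGene & is.na(cats)
    cats[fill] <- geneCat[parents[fill]]
  }

  keep <- !is.na(kind)
  fs <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(gr)[keep],
    ranges = IRanges::ranges(gr)[keep],
    strand = BiocGenerics::strand(gr)[keep]
  )
  S4Vectors::mcols(fs) <- S4Vectors::DataFrame(
    feature_id = ids[keep],
    gene_name = names_[keep],
    kind = kind[keep],
    parent_id = ifelse(is.na(parents[keep]), ids[keep], parents[keep]),
    functional_category = cats[keep]
  )
  if (length(fs) &&
      (min(BiocGenerics::start(fs)) < 1L ||
       max(BiocGenerics::end(fs)) > genomeLength)) {
    stopCoordinate("feature coordinates outside genome of length ",
      genomeLength)
  }
  GenomeInfoDb::seqlevels(fs) <-
    as.character(GenomeInfoDb::seqlevels(fs))
  GenomeInfoDb::seqlengths(fs) <- genomeLength
  fs
}

#' Derive flank UTRs for CDS features lacking explicit ones
#'
#' Adds, for each CDS without an explicit UTR on a given side, a 5'UTR of
#' `flank5` nt upstream and a 3'UTR of `flank3` nt downstream
#' (strand-aware), clipped at genome ends and at the nearest same-strand
#' feature. When two derived intervals on the same strand would collide
#' (the 3'UTR of one gene meeting the 5'UTR of the next), the overlap is
#' split at its midpoint, each interval truncated on the end away from
#' its parent CDS — derived UTRs therefore never overlap any same-strand
#' feature.
#'
#' @param fs a feature-set `GRanges` (see [readGff()]).
#' @param flank5,flank3 flank lengths in nt (defaults 100 and 50).
#' @return The feature set with derived UTR records appended
#'   (`feature_id` suffixed `.5utr`/`.3utr`, `parent_id` the CDS id).
#' @export
deriveUtrs <- function(fs, flank5 = 100L, flank3 = 50L) {
  glen <- GenomeInfoDb::seqlengths(fs)[1L]
  mc <- S4Vectors::mcols(fs)
  cdsIdx <- which(mc$kind == "CDS")
  if (!length(cdsIdx)) return(fs)
  hasUtr <- function(parent, kind) {
    any(mc$kind == kind & mc$parent_id == parent)
  }

  cand <- list() # each: list(start, end, strand, kind, parent, parentStart)
  for (i in cdsIdx) {
    st <- BiocGenerics::start(fs)[i]
    en <- BiocGenerics::end(fs)[i]
    sd <- as.character(BiocGenerics::strand(fs))[i]
    pid <- mc$parent_id[i]
    five <- if (sd == "+") c(st - flank5, st - 1L) else c(en + 1L, en + flank5)
    three <- if (sd == "+") c(en + 1L, en + flank3) else c(st - flank3, st - 1L)
    if (!hasUtr(pid, "five_prime_UTR")) {
      cand[[length(cand) + 1L]] <- list(
        start = five[1], end = five[2], strand = sd,
        kind = "five_prime_UTR", parent = pid, anchor = if (sd == "+") st else en
      )
    }
    if (!hasUtr(pid, "three_prime_UTR")) {
      cand[[length(cand) + 1L]] <- list(
        start = three[1], end = three[2], strand = sd,
        kind = "three_prime_UTR", parent = pid, anchor = if (sd == "+") en else st
      )
    }
  }
  if (!length(cand)) return(fs)

  # clip each candidate at genome ends and existing same-strand features,
  # shrinking toward the parent CDS
  clipOne <- function(cc) {
    a <- max(1L, cc$start)
    b <- min(glen, cc$end)
    if (a > b) return(NULL)
    same <- which(as.character(BiocGenerics::strand(fs)) == cc$strand)
    fst <- BiocGenerics::start(fs)[same]
    fen <- BiocGenerics::end(fs)[same]
    ov <- which(fst <= b & fen >= a)
    if (length(ov)) {
      if (cc$anchor > cc$end) { # candidate extends left of its parent
        a <- max(a, max(fen[ov]) + 1L)
      } else {                  # candidate extends right of its parent
        b <- min(b, min(fst[ov]) - 1L)
      }
      if (a > b) return(NULL)
    }
    cc$start <- a
    cc$end <- b
    cc
  }
  cand <- Filter(Negate(is.null), lapply(cand, clipOne))
  if (!length(cand)) return(fs)

  # resolve derived-derived collisions per strand: split overlaps at the
  # midpoint, each side truncated away from its parent
  for (sd in c("+", "-")) {
    ix <- which(vapply(cand, function(c) c$strand == sd, logical(1)))
    if (length(ix) < 2L) next
    ix <- ix[order(vapply(cand[ix], function(c) c$start, numeric(1)))]
    for (k in seq_len(length(ix) - 1L)) {
      a <- cand[[ix[k]]]
      b <- cand[[ix[k + 1L]]]
      if (is.null(a) || is.null(b)) next
      if (b$start <= a$end) {
        o1 <- max(a$start, b$start)
        o2 <- min(a$end, b$end)
        mid <- (o1 + o2) %/% 2L
        # the interval anchored on the left keeps the left part
        if (a$anchor <= b$anchor) {
          a$end <- mid
          b$start <- mid + 1L
        } else {
          b$end <- mid
          a$start <- mid + 1L
        }
        cand[[ix[k]]] <- if (a$start <= a$end) a else NULL
        cand[[ix[k + 1L]]] <- if (b$start <= b$end) b else NULL
      }
    }
  }
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) return(fs)

  derived <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqlevels(fs)[1L],
    ranges = IRanges::IRanges(
      start = vapply(cand, function(c) as.integer(c$start), integer(1)),
      end = vapply(cand, function(c) as.integer(c$end), integer(1))
    ),
    strand = vapply(cand, function(c) c$strand, character(1))
  )
  suffix <- ifelse(
    vapply(cand, function(c) c$kind, character(1)) == "five_prime_UTR",
    ".5utr", ".3utr"
  )
  parent <- vapply(cand, function(c) c$parent, character(1))
  pcat <- mc$functional_category[match(parent, mc$parent_id)]
  pname <- mc$gene_name[match(parent, mc$parent_id)]
  S4Vectors::mcols(derived) <- S4Vectors::DataFrame(
    feature_id = paste0(parent, suffix),
    gene_name = pname,
    kind = vapply(cand, function(c) c$kind, character(1)),
    parent_id = parent,
    functional_category = pcat
  )
  GenomeInfoDb::seqlengths(derived) <- glen
  out <- suppressWarnings(c(fs, derived))
  BiocGenerics::sort(out, ignore.strand = TRUE)
}

# classification rule for one peak against pre-extracted feature vectors
classifyInterval <- function(pStart, pEnd, pStrand, fStart, fEnd, fStrand,
                             fKind, fId) {
  ovw <- pmin(pEnd, fEnd) - pmax(pStart, fStart) + 1L
  hit <- which(ovw > 0L)
  if (!length(hit)) {
    return(list(
      category = "intergenic", feature_id = NA_character_, overlap_nt = 0L
    ))
  }
  prec <- match(fKind[hit], c(
    "five_prime_UTR", "three_prime_UTR", "RNA_gene", "CDS"
  ))
  width <- fEnd[hit] - fStart[hit] + 1L
  ord <- order(-ovw[hit], prec, width, fId[hit])
  best <- hit[ord[1L]]
  cat <- kindToCategory[[fKind[best]]]
  if (fStrand[best] != pStrand) cat <- paste0("as", cat)
  list(
    category = cat, feature_id = fId[best],
    overlap_nt = as.integer(ovw[best])
  )
}

#' Assign each peak a genomic category and a feature
#'
#' Among all features overlapping the peak on either strand, the one with
#' maximal overlap in nt wins; ties are broken by kind precedence
#' 5'UTR > 3'UTR > RNA gene > CDS, then by smaller feature, then by
#' lexicographic feature id. The category is the winning feature's kind,
#' prefixed `as` when the feature lies on the strand opposite the peak —
#' sense and antisense features compete on equal footing. Peaks
#' overlapping nothing are `intergenic`.
#'
#' @param peaks a `GRanges` of peaks (see [callPeaks()]).
#' @param fs a feature-set `GRanges` (see [readGff()], [deriveUtrs()]).
#' @return `peaks` with added metadata columns `category`,
#'   `assigned_feature`, `gene_id` (the feature's parent gene) and
#'   `overlap_nt`.
#' @export
annotatePeaks <- function(peaks, fs) {
  mc <- S4Vectors::mcols(fs)
  fStart <- BiocGenerics::start(fs)
  fEnd <- BiocGenerics::end(fs)
  fStrand <- as.character(BiocGenerics::strand(fs))
  res <- lapply(seq_along(peaks), function(k) {
    classifyInterval(
      BiocGenerics::start(peaks)[k], BiocGenerics::end(peaks)[k],
      as.character(BiocGenerics::strand(peaks))[k],
      fStart, fEnd, fStrand, mc$kind, mc$feature_id
    )
  })
  feat <- vapply(res, function(r) r$feature_id, character(1))
  S4Vectors::mcols(peaks)$category <- vapply(
    res, function(r) r$category, character(1)
  )
  S4Vectors::mcols(peaks)$assigned_feature <- feat
  S4Vectors::mcols(peaks)$gene_id <-
    mc$parent_id[match(feat, mc$feature_id)]
  S4Vectors::mcols(peaks)$overlap_nt <- vapply(
    res, function(r) r$overlap_nt, integer(1)
  )
  peaks
}

#' Collapse annotated peaks to unique target genes
#'
#' Groups peaks by the parent gene of their assigned feature. Sense
#' categories (CDS, UTRs, RNA) map to the gene itself; antisense
#' categories map to the sense gene the peak opposes and are reported in
#' a separate antisense list. Intergenic peaks are dropped.
#'
#' @param annotated an annotated peak `GRanges` (see [annotatePeaks()]).
#' @return A list with elements `sense` and `antisense`, each a
#'   `data.frame` with columns `gene_id`, `n_peaks` and a list-column
#'   `peak_ids`.
#' @export
peaksToGenes <- function(annotated) {
  mc <- S4Vectors::mcols(annotated)
  groupUp <- function(sel) {
    if (!any(sel)) {
      return(data.frame(
        gene_id = character(0), n_peaks = integer(0)
      ))
    }
    sp <- split(mc$peak_id[sel], mc$gene_id[sel])
    out <- data.frame(
      gene_id = names(sp), n_peaks = lengths(sp),
      row.names = NULL, stringsAsFactors = FALSE
    )
    out$peak_ids <- unname(sp)
    out[order(out$gene_id), , drop = FALSE]
  }
  isAs <- startsWith(mc$category, "as")
  isGenic <- mc$category != "intergenic"
  list(
    sense = groupUp(isGenic & !isAs),
    antisense = groupUp(isGenic & isAs)
  )
}

#' Relative distribution of peaks over genomic categories
#'
#' @param annotated a non-empty annotated peak `GRanges`.
#' @return Named numeric over the nine categories (see
#'   [peakCategories()]); the fractions sum to 1.
#' @export
categoryDistribution <- function(annotated) {
  if (!length(annotated)) stopDomain("no annotated peaks")
  cats <- S4Vectors::mcols(annotated)$category
  tab <- table(factor(cats, levels = peakCategories()))
  stats::setNames(as.numeric(tab) / length(annotated), peakCategories())
}
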