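#' @import methods
#' @importFrom BiocGenerics strand
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' CoverageTrack: strand-specific per-nucleotide coverage
#'
#' A `CoverageTrack` holds normalized or raw read coverage for one strand of
#' one sequencing library (or a replicate mean), with one value per genomic
#' position `1..length`. Positions are 1-based and contiguous; positions with
#' no datum in the source file hold 0. Reverse-strand tracks use
#' forward-strand coordinates throughout — coordinates never flip.
#'
#' @slot genomeId single replicon identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot values numeric vector of non-negative, finite coverage values.
#' @slot label library name.
#' @slot normalized has [normalizeToLibrarySize()] been applied?
#'
#' @seealso [CoverageTrack()], [readWiggle()], [readGrp()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(
    genomeId = "character",
    strand = "character",
    values = "numeric",
    label = "character",
    normalized = "logical"
  )
)

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L) msg <- c(msg, "'genomeId' must be a single string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  if (length(object@values) < 1L) msg <- c(msg, "'values' must be non-empty")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "coverage values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "coverage values must be non-negative")
  if (length(object@label) != 1L) msg <- c(msg, "'label' must be a single string")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msg <- c(msg, "'normalized' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param values numeric vector of non-negative coverage values, one per
#'   genomic position starting at 1.
#' @param strand `"+"`/`"-"`; the aliases `"F"`/`"R"` and
#'   `"forward"`/`"reverse"` are accepted.
#' @param genomeId replicon identifier.
#' @param label library name.
#' @param normalized whether the values are already library-size normalized.
#' @return A [CoverageTrack-class] object.
#' @examples
#' tr <- CoverageTrack(c(0, 3, 5), strand = "F", label = "rep1")
#' trackLength(tr)
#' @export
CoverageTrack <- function(values, strand, genomeId = "genome", label = "",
                          normalized = FALSE) {
  new("CoverageTrack",
    genomeId = as.character(genomeId),
    strand = normalizeStrand(strand),
    values = as.numeric(values),
    label = as.character(label),
    normalized = isTRUE(normalized)
  )
}

normalizeStrand <- function(strand) {
  s <- as.character(strand)[1L]
  out <- c(
    "+" = "+", "-" = "-", "F" = "+", "R" = "-",
    "forward" = "+", "reverse" = "-", "f" = "+", "r" = "-"
  )[s]
  if (is.na(out)) {
    stopDomain("unknown strand designation: ", sQuote(s))
  }
  unname(out)
}

#' GrpFile: a per-strand multi-library coverage table
#'
#' The grp dialect is a plain-text per-nucleotide coverage table: one line
#' per genomic position, one tab-separated column per library, one file per
#' strand. Body line `k` corresponds to genomic position `k` (1-based).
#'
#' @slot genomeId replicon identifier.
#' @slot strand `"+"` or `"-"` (written as `F`/`R`).
#' @slot labels library names, one per column.
#' @slot matrix numeric matrix, `length x n_libraries`, non-negative.
#'
#' @seealso [readGrp()], [writeGrp()], [grpFromTracks()], [grpToTracks()]
#' @exportClass GrpFile
setClass("GrpFile",
  representation(
    genomeId = "character",
    strand = "character",
    labels = "character",
    matrix = "matrix"
  )
)

setValidity("GrpFile", function(object) {
  msg <- character()
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  if (!is.numeric(object@matrix)) msg <- c(msg, "'matrix' must be numeric")
  if (ncol(object@matrix) != length(object@labels))
    msg <- c(msg, "number of columns must equal number of labels")
  if (nrow(object@matrix) < 1L) msg <- c(msg, "matrix must have at least one row")
  if (anyNA(object@matrix) || any(!is.finite(object@matrix)))
    msg <- c(msg, "coverage values must be finite")
  else if (any(object@matrix < 0))
    msg <- c(msg, "coverage values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a GrpFile
#'
#' @param matrix numeric matrix of coverage values (positions x libraries).
#' @param labels library names, one per column.
#' @param strand `"+"`/`"-"` (or `F`/`R`).
#' @param genomeId replicon identifier.
#' @return A [GrpFile-class] object.
#' @export
GrpFile <- function(matrix, labels, strand, genomeId = "genome") {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  new("GrpFile",
    genomeId = as.character(genomeId),
    strand = normalizeStrand(strand),
    labels = as.character(labels),
    matrix = m
  )
}
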