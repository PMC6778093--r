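#' Read a wiggle file into a zero-filled CoverageTrack
#'
#' Parses a standard `variableStep`/`fixedStep` wiggle file (span 1 only)
#' and returns per-nucleotide coverage over the full genome. Positions
#' absent from the file are set to 0, so the track is contiguous from
#' position 1 to `genomeLength`.
#'
#' @param path path to a wiggle file.
#' @param genomeLength length of the (single) replicon in nt.
#' @param strand strand the file describes (`"+"`/`"-"`, `F`/`R` accepted).
#' @param label library name to attach to the track.
#' @param genomeId replicon identifier for the returned track.
#' @return A [CoverageTrack-class] of exactly `genomeLength` values.
#' @examples
#' wig <- tempfile(fileext = ".wig")
#' writeLines(c("variableStep chrom=chr", "1\t4", "2\t4", "5\t2"), wig)
#' tr <- readWiggle(wig, genomeLength = 6, strand = "F", label = "rep1")
#' coverageValues(tr) # 4 4 0 0 2 0
#' @export
readWiggle <- function(path, genomeLength, strand, label = basename(path),
                       genomeId = "genome") {
  if (!file.exists(path)) stopIO("wiggle file not found: ", path)
  genomeLength <- as.integer(genomeLength)
  if (is.na(genomeLength) || genomeLength < 1L) {
    stopDomain("'genomeLength' must be a positive integer")
  }
  lines <- readLines(path, warn = FALSE)
  ndata <- validateWiggleLines(lines, path)
  if (ndata == 0L) {
    return(CoverageTrack(numeric(genomeLength), strand,
      genomeId = genomeId, label = label
    ))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "wig"),
    error = function(e) stopParse("failed to parse wiggle ", path, ": ",
      conditionMessage(e))
  )
  if (length(gr) && any(BiocGenerics::width(gr) != 1L)) {
    stopParse("wiggle spans > 1 are not supported (one value per nucleotide)")
  }
  pos <- BiocGenerics::start(gr)
  if (length(pos) && (min(pos) < 1L || max(pos) > genomeLength)) {
    stopCoordinate(
      "wiggle position ", max(pos),
      " exceeds genome length ", genomeLength
    )
  }
  val <- S4Vectors::mcols(gr)$score
  if (any(val < 0)) stopDomain("negative coverage value in ", path)
  values <- numeric(genomeLength)
  values[pos] <- val
  CoverageTrack(values, strand, genomeId = genomeId, label = label)
}

# Light structural check so malformed lines are reported with their line
# number (the underlying importer's message does not carry one). Returns
# the number of data lines.
validateWiggleLines <- function(lines, path) {
  ndata <- 0L
  mode <- NA_character_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) {
      next
    }
    if (startsWith(ln, "variableStep") || startsWith(ln, "fixedStep")) {
      mode <- if (startsWith(ln, "fixedStep")) "fixed" else "variable"
      next
    }
    fields <- strsplit(ln, "[\t ]+")[[1]]
    ok <- if (identical(mode, "fixed")) {
      length(fields) == 1L && !is.na(suppressWarnings(as.numeric(fields)))
    } else {
      length(fields) == 2L &&
        !anyNA(suppressWarnings(as.numeric(fields)))
    }
    if (is.na(mode) || !ok) {
      stopParse("malformed wiggle line ", i, " in ", path, ": ", sQuote(ln))
    }
    ndata <- ndata + 1L
  }
  ndata
}

#' Read a grp coverage table
#'
#' The grp dialect is plain text (UTF-8, LF): line 1
#' `# genome=<id> strand=<F|R> length=<L>`; line 2
#' `# libs=<tab-separated labels>`; then exactly `L` data lines, each a
#' tab-separated non-negative decimal per library. Body line `k` is genomic
#' position `k` (1-based).
#'
#' @param path path to a grp file.
#' @return A [GrpFile-class] object.
#' @seealso [writeGrp()], [grpToTracks()]
#' @export
readGrp <- function(path) {
  if (!file.exists(path)) stopIO("grp file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stopParse("grp file too short: ", path)
  h1 <- regmatches(
    lines[1L],
    regexec("^# genome=(\\S+) strand=([FR]) length=([0-9]+)$", lines[1L])
  )[[1]]
  if (length(h1) != 4L) {
    stopParse("malformed grp header line 1 in ", path, ": ", sQuote(lines[1L]))
  }
  if (!startsWith(lines[2L], "# libs=")) {
    stopParse("malformed grp header line 2 in ", path, ": ", sQuote(lines[2L]))
  }
  labels <- strsplit(sub("^# libs=", "", lines[2L]), "\t", fixed = TRUE)[[1]]
  len <- as.integer(h1[4L])
  body <- lines[-(1:2)]
  if (length(body) != len) {
    stopParse(
      "grp body has ", length(body), " lines but header declares length ", len
    )
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(labels))) {
    bad <- which(nf != length(labels))[1L]
    stopParse(
      "grp body line ", bad, " has ", nf[bad], " fields, expected ",
      length(labels)
    )
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) stopParse("non-numeric coverage value in ", path)
  if (any(vals < 0)) stopDomain("negative coverage value in ", path)
  m <- matrix(vals, nrow = len, ncol = length(labels), byrow = TRUE)
  GrpFile(m, labels = labels, strand = h1[3L], genomeId = h1[2L])
}

#' Write a grp coverage table
#'
#' Produces canonical, deterministic text output: identical inputs yield
#' byte-identical files. Values are printed with up to 6 significant
#' digits; a file written and re-read reproduces its values to that
#' precision.
#'
#' @param grp a [GrpFile-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrp <- function(grp, path) {
  stopifnot(is(grp, "GrpFile"))
  validObject(grp)
  m <- grp@matrix
  strandCode <- if (grp@strand == "+") "F" else "R"
  header <- c(
    sprintf("# genome=%s strand=%s length=%d", grp@genomeId, strandCode, nrow(m)),
    paste0("# libs=", paste(grp@labels, collapse = "\t"))
  )
  txt <- matrix(formatCoverage(m), nrow = nrow(m))
  body <- do.call(paste, c(lapply(seq_len(ncol(txt)), function(j) txt[, j]),
    sep = "\t"
  ))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Bundle single-library tracks into a GrpFile
#'
#' @param tracks list of [CoverageTrack-class] objects sharing genome,
#'   strand and length; column order follows the list order.
#' @return A [GrpFile-class] with one column per track.
#' @export
grpFromTracks <- function(tracks) {
  if (!length(tracks)) stopDomain("empty track list")
  checkSameShape(tracks)
  m <- vapply(tracks, coverageValues, numeric(trackLength(tracks[[1]])))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(tracks))
  GrpFile(m,
    labels = vapply(tracks, trackLabel, character(1)),
    strand = strand(tracks[[1]]), genomeId = genomeId(tracks[[1]])
  )
}

#' Split a GrpFile into per-library CoverageTracks
#'
#' @param grp a [GrpFile-class].
#' @param normalized whether the stored values are library-size normalized
#'   (the grp format itself does not record this).
#' @return Named list of [CoverageTrack-class] objects, one per column.
#' @export
grpToTracks <- function(grp, normalized = FALSE) {
  stopifnot(is(grp, "GrpFile"))
  out <- lapply(seq_along(grp@labels), function(j) {
    CoverageTrack(grp@matrix[, j], grp@strand,
      genomeId = grp@genomeId, label = grp@labels[j], normalized = normalized
    )
  })
  names(out) <- grp@labels
  out
}

#' Normalize a coverage track to library size
#'
#' Scales every value by `scale / totalMappedReads`, the reads-per-million
#' convention when `scale = 1e6`. Normalizing an already-normalized track
#' is an error: normalization is applied exactly once per library.
#'
#' @param track a raw [CoverageTrack-class].
#' @param totalMappedReads library size. If `NULL`, defaults to the raw
#'   value sum of the track itself plus any tracks in `companions`
#'   (typically the library's other strand), so a library can be
#'   normalized without access to the original alignments.
#' @param scale positive scale constant (default `1e6`). Downstream peak
#'   calls are invariant to this choice.
#' @param companions optional list of tracks whose raw sums contribute to
#'   the default library size.
#' @return The normalized [CoverageTrack-class].
#' @examples
#' tr <- CoverageTrack(c(10, 0, 30), "F")
#' coverageValues(normalizeToLibrarySize(tr, 2e6)) # 5 0 15
#' @export
normalizeToLibrarySize <- function(track, totalMappedReads = NULL,
                                   scale = 1e6, companions = list()) {
  stopifnot(is(track, "CoverageTrack"))
  if (isNormalized(track)) {
    stopState("track ", sQuote(trackLabel(track)), " is already normalized")
  }
  if (is.null(totalMappedReads)) {
    totalMappedReads <- sum(coverageValues(track)) +
      sum(vapply(companions, function(t) sum(coverageValues(t)), numeric(1)))
  }
  if (!is.numeric(totalMappedReads) || length(totalMappedReads) != 1L ||
      is.na(totalMappedReads) || totalMappedReads <= 0) {
    stopDomain("'totalMappedReads' must be a positive number")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stopDomain("'scale' must be a positive number")
  }
  CoverageTrack(coverageValues(track) * (scale / totalMappedReads),
    strand(track),
    genomeId = genomeId(track), label = trackLabel(track), normalized = TRUE
  )
}

#' Merge replicate tracks positionwise
#'
#' @param tracks list of [CoverageTrack-class] objects sharing genome,
#'   strand, length and normalization status.
#' @param reducer `"mean"` (replicate averaging, the default) or `"sum"`.
#' @return A single merged [CoverageTrack-class]; its label concatenates
#'   the input labels.
#' @export
mergeTracks <- function(tracks, reducer = c("mean", "sum")) {
  reducer <- match.arg(reducer)
  if (!length(tracks)) stopDomain("empty track list")
  checkSameShape(tracks)
  m <- vapply(tracks, coverageValues, numeric(trackLength(tracks[[1]])))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(tracks))
  v <- if (reducer == "mean") rowMeans(m) else rowSums(m)
  CoverageTrack(v, strand(tracks[[1]]),
    genomeId = genomeId(tracks[[1]]),
    label = paste(vapply(tracks, trackLabel, character(1)), collapse = "+"),
    normalized = isNormalized(tracks[[1]])
  )
}
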