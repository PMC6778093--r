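#' @rdname CoverageTrack-class
#' @param object,x a [CoverageTrack-class] or [GrpFile-class] object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("coverageValues", function(x) standardGeneric("coverageValues"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackLength", function(x) standardGeneric("trackLength"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname GrpFile-class
#' @export
setGeneric("grpLabels", function(x) standardGeneric("grpLabels"))

#' @rdname GrpFile-class
#' @export
setGeneric("grpMatrix", function(x) standardGeneric("grpMatrix"))

#' @rdname CoverageTrack-class
#' @export
setMethod("genomeId", "CoverageTrack", function(x) x@genomeId)

#' @rdname CoverageTrack-class
#' @export
setMethod("coverageValues", "CoverageTrack", function(x) x@values)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackLabel", "CoverageTrack", function(x) x@label)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackLength", "CoverageTrack", function(x) length(x@values))

#' @rdname CoverageTrack-class
#' @export
setMethod("isNormalized", "CoverageTrack", function(x) x@normalized)

#' @rdname CoverageTrack-class
#' @importFrom BiocGenerics strand
#' @export
setMethod("strand", "CoverageTrack", function(x) x@strand)

#' @rdname GrpFile-class
#' @export
setMethod("genomeId", "GrpFile", function(x) x@genomeId)

#' @rdname GrpFile-class
#' @export
setMethod("strand", "GrpFile", function(x) x@strand)

#' @rdname GrpFile-class
#' @export
setMethod("grpLabels", "GrpFile", function(x) x@labels)

#' @rdname GrpFile-class
#' @export
setMethod("grpMatrix", "GrpFile", function(x) x@matrix)

#' @rdname GrpFile-class
#' @export
setMethod("trackLength", "GrpFile", function(x) nrow(x@matrix))

#' @rdname CoverageTrack-class
setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf(
    "CoverageTrack '%s' on %s(%s): %d nt, mean %.4g, %s\n",
    object@label, object@genomeId, object@strand, length(object@values),
    mean(object@values),
    if (object@normalized) "normalized" else "raw"
  ))
})

#' @rdname GrpFile-class
setMethod("show", "GrpFile", function(object) {
  cat(sprintf(
    "GrpFile on %s(%s): %d nt x %d libraries (%s)\n",
    object@genomeId, object@strand, nrow(object@matrix),
    ncol(object@matrix), paste(object@labels, collapse = ", ")
  ))
})
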