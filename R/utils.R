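# Condition helpers: every error carries a crafd_error class plus a
# specific subclass so callers (and the command-line wrapper) can map
# failures to exit codes without string matching.

crafdStop <- function(subclass, ...) {
  stop(errorCondition(paste0(...), class = c(subclass, "crafd_error", "error")))
}

stopParse <- function(...) crafdStop("crafd_parse_error", ...)
stopCoordinate <- function(...) crafdStop("crafd_coordinate_error", ...)
stopDomain <- function(...) crafdStop("crafd_domain_error", ...)
stopState <- function(...) crafdStop("crafd_state_error", ...)
stopIncompatible <- function(...) crafdStop("crafd_incompatibility_error", ...)
stopIO <- function(...) crafdStop("crafd_io_error", ...)

# Rolling mean of width w over v: result[i] = mean(v[i..i+w-1]),
# defined for i in 1..(length(v)-w+1).
rollMean <- function(v, w) {
  cs <- c(0, cumsum(v))
  n <- length(v) - w + 1L
  if (n < 1L) return(numeric(0))
  (cs[(w + 1L):(w + n)] - cs[1:n]) / w
}

# format a coverage value for grp output: up to 6 significant digits,
# integers printed without a decimal part
formatCoverage <- function(x) {
  sprintf("%.6g", x)
}

checkSameShape <- function(tracks) {
  gid <- vapply(tracks, genomeId, character(1))
  str <- vapply(tracks, strand, character(1))
  len <- vapply(tracks, trackLength, integer(1))
  nrm <- vapply(tracks, isNormalized, logical(1))
  if (length(unique(gid)) != 1L || length(unique(str)) != 1L ||
      length(unique(len)) != 1L) {
    stopIncompatible("tracks differ in genome, strand or length")
  }
  if (length(unique(nrm)) != 1L) {
    stopIncompatible("tracks mix normalized and raw coverage")
  }
  invisible(TRUE)
}
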