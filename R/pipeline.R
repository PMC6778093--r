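writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
    eol = "\n"
  )
  invisible(path)
}

#' Convert a peak GRanges to a plain table
#'
#' @param peaks a peak `GRanges` (possibly with enrichment / annotation
#'   columns).
#' @return A `data.frame` with `peak_id`, `strand`, `start`, `end`,
#'   `length`, `mean_coverage` and any further metadata columns.
#' @export
peaksToTable <- function(peaks) {
  mc <- as.data.frame(S4Vectors::mcols(peaks))
  base <- data.frame(
    peak_id = mc$peak_id,
    strand = as.character(BiocGenerics::strand(peaks)),
    start = BiocGenerics::start(peaks),
    end = BiocGenerics::end(peaks),
    length = BiocGenerics::width(peaks),
    stringsAsFactors = FALSE
  )
  extra <- mc[, setdiff(names(mc), c("peak_id")), drop = FALSE]
  listCols <- vapply(extra, is.list, logical(1))
  cbind(base, extra[, !listCols, drop = FALSE])
}

#' Export peaks to BED6
#'
#' BED is 0-based half-open; the conversion (start minus 1, end
#' unchanged) is handled by the exporter.
#'
#' @param peaks a peak `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportPeaksBed <- function(peaks, path) {
  bed <- peaks
  S4Vectors::mcols(bed) <- S4Vectors::DataFrame(
    name = paste0("peak_", S4Vectors::mcols(peaks)$peak_id),
    score = S4Vectors::mcols(peaks)$mean_coverage
  )
  rtracklayer::export(bed, path, format = "bed")
  invisible(path)
}

defaultPipelineConfig <- function() {
  list(
    simulate = NULL, # a simulationConfig()-style list, or NULL
    pulldown = NULL, # list of replicates: list(fwd = path, rev = path)
    control = NULL,  # list(fwd = path, rev = path)
    totals = NULL,   # optional named per-library sizes
    gff = NULL,
    genomeLength = NULL,
    deriveUtrs = FALSE, flank5 = 100L, flank3 = 50L,
    ranks = NULL,    # optional TSV: peak_id, rank
    peakParams = list(), enrichParams = list(),
    alpha = 0.05,
    outdir = "crafd_out",
    seed = 1L
  )
}

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopIO("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stopIO("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    }
  }
  cfg <- defaultPipelineConfig()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    crafdStop(
      class(e)[1L],
      "pipeline stage '", name, "' failed: ", conditionMessage(e)
    )
  })
}

#' Run the full analysis pipeline
#'
#' Mirrors the study's stage order: library-size normalization, replicate
#' merging per strand, peak calling on the merged pull-down coverage,
#' replicate-consensus enrichment calling against the control, genomic
#' category annotation, and the downstream statistics. Writes
#' `peaks.tsv`, `enrichment.tsv`, `annot.tsv`,
#' `category_distribution.tsv`, `category_enrichment.tsv`,
#' `rank_test.tsv` (when ranks are supplied) and a `manifest.json`
#' recording every parameter used; re-running from the manifest
#' reproduces the outputs byte-identically.
#'
#' @param config a named list, or a path to a JSON/YAML file with the
#'   same structure (a manifest from a previous run works). Fields:
#'   `pulldown` (list of replicates, each `list(fwd=, rev=)` grp paths),
#'   `control` (`list(fwd=, rev=)`), optional `totals` (named library
#'   sizes), `gff`, `deriveUtrs`/`flank5`/`flank3`, optional `ranks`
#'   TSV, `peakParams`, `enrichParams`, `alpha`, `outdir`, `seed`, and
#'   optionally `simulate` (a [simulationConfig()]-style list) to
#'   generate the inputs first.
#' @param quiet suppress stage progress messages?
#' @return The output directory, invisibly; side effect: result tables
#'   and the manifest under `outdir`.
#' @export
runAll <- function(config, quiet = FALSE) {
  cfg <- readPipelineConfig(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (!quiet) message("[crafdseq] ", ...)

  if (!is.null(cfg$simulate)) {
    note("simulating input libraries")
    simArgs <- cfg$simulate
    if (isTRUE(simArgs)) simArgs <- list()
    simArgs$seed <- simArgs$seed %||% cfg$seed
    scfg <- do.call(simulationConfig, simArgs)
    fixdir <- file.path(outdir, "fixtures")
    dir.create(fixdir, showWarnings = FALSE, recursive = TRUE)
    gffPath <- file.path(fixdir, "annotation.gff3")
    fs <- simulateAnnotation(scfg, gffPath = gffPath)
    sim <- simulateLibraries(scfg, fs)
    paths <- writeSimulatedGrp(sim, fixdir)
    writeTsv(sim$truth, file.path(fixdir, "truth.tsv"))
    cfg$pulldown <- paths$pulldown
    cfg$control <- paths$control
    cfg$gff <- gffPath
    cfg$genomeLength <- scfg$genomeLength
    cfg$simulate <- simArgs
  }

  if (is.null(cfg$pulldown) || !length(cfg$pulldown)) {
    stage("coverage", stopIO("no pull-down libraries configured"))
  }
  if (is.null(cfg$control)) {
    stage("enrichment", stopIO("no control library configured"))
  }

  note("reading and normalizing coverage")
  loadLib <- function(paths, label) {
    stage("coverage", {
      fwd <- grpToTracks(readGrp(paths$fwd))[[1L]]
      rev <- grpToTracks(readGrp(paths$rev))[[1L]]
      total <- if (!is.null(cfg$totals) && label %in% names(cfg$totals)) {
        cfg$totals[[label]]
      } else {
        NULL
      }
      list(
        fwd = normalizeToLibrarySize(fwd, total, companions = list(rev)),
        rev = normalizeToLibrarySize(rev, total, companions = list(fwd))
      )
    })
  }
  repLabels <- sprintf("rep%d", seq_along(cfg$pulldown))
  reps <- Map(loadLib, cfg$pulldown, repLabels)
  ctrl <- loadLib(cfg$control, "control")

  note("merging replicates and calling peaks")
  pparams <- stage("peak_calling", do.call(peakCallParams, cfg$peakParams))
  merged <- stage("peak_calling", list(
    fwd = mergeTracks(lapply(reps, `[[`, "fwd")),
    rev = mergeTracks(lapply(reps, `[[`, "rev"))
  ))
  peaks <- stage(
    "peak_calling", callPeaksBothStrands(merged$fwd, merged$rev, pparams)
  )
  writeTsv(peaksToTable(peaks), file.path(outdir, "peaks.tsv"))

  note("classifying enrichment against the control")
  eparams <- stage("enrichment", do.call(enrichmentParams, cfg$enrichParams))
  enriched <- stage("enrichment", {
    perStrand <- lapply(c("+", "-"), function(sd) {
      sel <- as.character(BiocGenerics::strand(peaks)) == sd
      side <- if (sd == "+") "fwd" else "rev"
      classifyPeaks(
        peaks[sel], lapply(reps, `[[`, side), ctrl[[side]], eparams
      )
    })
    suppressWarnings(do.call(c, perStrand))
  })
  enriched <- enriched[order(S4Vectors::mcols(enriched)$peak_id)]
  writeTsv(peaksToTable(enriched), file.path(outdir, "enrichment.tsv"))

  annotated <- NULL
  if (!is.null(cfg$gff)) {
    note("annotating peaks")
    annotated <- stage("annotation", {
      glen <- cfg$genomeLength %||% trackLength(merged$fwd)
      fs <- readGff(cfg$gff, glen)
      if (isTRUE(cfg$deriveUtrs)) {
        fs <- deriveUtrs(fs, cfg$flank5, cfg$flank3)
      }
      annotatePeaks(enriched, fs)
    })
    writeTsv(
      peaksToTable(annotated)[, c(
        "peak_id", "strand", "start", "end", "status", "category",
        "assigned_feature", "gene_id", "overlap_nt"
      )],
      file.path(outdir, "annot.tsv")
    )
    isEnr <- S4Vectors::mcols(annotated)$status == "enriched"
    if (any(isEnr)) {
      dist <- categoryDistribution(annotated[isEnr])
      writeTsv(
        data.frame(category = names(dist), fraction = as.numeric(dist)),
        file.path(outdir, "category_distribution.tsv")
      )
      note("functional-category enrichment")
      stage("stats", {
        glen <- cfg$genomeLength %||% trackLength(merged$fwd)
        fs <- readGff(cfg$gff, glen)
        bg <- backgroundCategories(fs)
        targets <- unique(stats::na.omit(
          S4Vectors::mcols(annotated)$gene_id[isEnr]
        ))
        targets <- intersect(targets, names(bg))
        if (length(targets)) {
          writeTsv(
            categoryEnrichment(targets, bg, alpha = cfg$alpha),
            file.path(outdir, "category_enrichment.tsv")
          )
        }
      })
    }
  }

  if (!is.null(cfg$ranks)) {
    note("rank comparison of enriched vs non-enriched peaks")
    stage("stats", {
      ranks <- utils::read.delim(cfg$ranks)
      tab <- merge(
        peaksToTable(enriched)[, c("peak_id", "status")], ranks,
        by = "peak_id"
      )
      res <- compareEnrichedRanks(tab)
      writeTsv(
        data.frame(
          H = res$H, p_value = res$p_value, method = res$method,
          median_rank_enriched = res$medians[["enriched"]],
          median_rank_not_enriched = res$medians[["not_enriched"]],
          direction = res$direction
        ),
        file.path(outdir, "rank_test.tsv")
      )
    })
  }

  manifest <- cfg
  manifest$peakParams <- unclass(pparams)
  manifest$enrichParams <- unclass(eparams)
  manifest$package_version <- as.character(utils::packageVersion("crafdseq"))
  jsonlite::write_json(
    manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene functional categories from a feature set
#'
#' @param fs a feature-set `GRanges`.
#' @return Named list mapping each gene (`parent_id`) to its character
#'   vector of functional categories (empty when unannotated).
#' @export
backgroundCategories <- function(fs) {
  mc <- S4Vectors::mcols(fs)
  sp <- split(mc$functional_category, mc$parent_id)
  lapply(sp, function(x) sort(unique(x[!is.na(x)])))
}

# write one single-column grp per library and strand; returns the path
# lists runAll expects
writeSimulatedGrp <- function(sim, dir) {
  wr <- function(track, name) {
    p <- file.path(dir, name)
    writeGrp(grpFromTracks(list(track)), p)
    p
  }
  pulldown <- lapply(seq_along(sim$pulldown), function(r) {
    list(
      fwd = wr(sim$pulldown[[r]]$fwd, sprintf("pulldown_rep%d_fwd.grp", r)),
      rev = wr(sim$pulldown[[r]]$rev, sprintf("pulldown_rep%d_rev.grp", r))
    )
  })
  control <- list(
    fwd = wr(sim$control$fwd, "control_fwd.grp"),
    rev = wr(sim$control$rev, "control_rev.grp")
  )
  list(pulldown = pulldown, control = control)
}
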