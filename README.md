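# crafdseq

Peak calling and enrichment analysis for sRNA affinity pull-down
sequencing (CRAFD-Seq) data.

## The problem

Small regulatory RNAs (sRNAs) act by base-pairing with target
transcripts. CRAFD-Seq maps an sRNA's targetome biochemically: a
biotinylated bait sRNA immobilized on streptavidin beads captures
interacting RNAs from cell lysate, the captured RNA is sequenced in
duplicate, and an empty-bead control library separates genuine
capture from background. What remains is a data-analysis problem,
which this package solves for anyone running such pull-down or
enrichment-sequencing experiments on compact (bacterial-scale)
genomes:

1. **Coverage ingestion** — strand-specific per-nucleotide coverage
   (grp tables, one line per genomic position, or standard wiggle) is
   zero-filled, normalized to library size (reads-per-million style)
   and merged across replicates.
2. **Peak calling** — a sliding-window fold-change detector. With
   window *w* = 5 nt, spacer *s* = 10 nt and threshold *f* = 1.5, a
   start boundary is placed at position *i* when
   mean(cov[i..i+w−1]) / mean(cov[i−s−w..i−s−1]) ≥ *f* (an end
   boundary symmetrically), both means offset by a small pseudocount.
   Boundaries are paired left to right, and a called interval is kept
   only if its mean coverage is at least *c* = 20% of the
   dataset-wide mean coverage per nucleotide.
3. **Enrichment calling** — each peak's mean coverage is compared with
   the control per replicate; a peak is *enriched* when **every**
   replicate is more than 2-fold above control, *partially enriched*
   when only some are, *not enriched* otherwise.
4. **Annotation** — peaks are classified by maximal overlap into CDS,
   5′UTR, 3′UTR and RNA-gene categories, with antisense counterparts
   (asCDS, as5′UTR, as3′UTR, asRNA) when the feature lies on the
   opposite strand, and collapsed to unique target genes.
5. **Statistics** — exact one-sided hypergeometric enrichment of
   functional categories among target genes (with
   Benjamini–Hochberg correction), and a Kruskal-Wallis rank test
   comparing whole-genome interaction-prediction ranks (e.g. intaRNA)
   of enriched versus non-enriched peaks.

A synthetic-data module simulates annotated genomes and
pull-down/control libraries with planted multiplicative peaks and
known ground truth, so the whole pipeline is testable without any
external download.

## Worked example

Call a peak on a noiseless coverage step (10 → 20 → 10 over 200 nt):

```r
library(crafdseq)
tr <- CoverageTrack(c(rep(10, 50), rep(20, 70), rep(10, 80)), "F",
                    label = "demo", normalized = TRUE)
callPeaks(tr)
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames    ranges strand |   peak_id mean_coverage source_label
#>          <Rle> <IRanges>  <Rle> | <integer>     <numeric>  <character>
#>   [1]   genome    51-120      + |         1            20         demo
```

The boundaries land exactly on the first and last elevated base; the
peak's mean coverage (20) clears the dataset filter (20% of 13.5).

A complete synthetic study — simulate, normalize, call, classify,
score against the planted truth:

```r
cfg <- simulationConfig(seed = 42)          # 50 kb genome, 30 true peaks,
fs  <- simulateAnnotation(cfg)              # 10 decoys, duplicate libraries
sim <- simulateLibraries(cfg, fs)

norm <- function(t, comp) normalizeToLibrarySize(t, companions = list(comp))
reps <- lapply(sim$pulldown, function(r)
  list(fwd = norm(r$fwd, r$rev), rev = norm(r$rev, r$fwd)))
ctrl <- list(fwd = norm(sim$control$fwd, sim$control$rev),
             rev = norm(sim$control$rev, sim$control$fwd))
merged <- list(fwd = mergeTracks(lapply(reps, `[[`, "fwd")),
               rev = mergeTracks(lapply(reps, `[[`, "rev")))
peaks <- callPeaksBothStrands(merged$fwd, merged$rev)
calls <- suppressWarnings(do.call(c, lapply(c("+", "-"), function(sd) {
  side <- if (sd == "+") "fwd" else "rev"
  classifyPeaks(peaks[as.character(BiocGenerics::strand(peaks)) == sd],
                lapply(reps, `[[`, side), ctrl[[side]])
})))
table(S4Vectors::mcols(calls)$status)
#>           enriched partially_enriched       not_enriched
#>                 29                  0                  2

scoreRecovery(calls, sim$truth)
#> Recovery of planted peaks: recall 0.967, precision 1.000 (29 calls, 29 matched)
#>   median boundary error 5 nt; decoys called enriched: 0
```

29 of the 30 planted peaks are recovered as enriched with tight
boundaries; the two sub-threshold decoys that were called as peaks
are correctly left non-enriched, and none of the 10 decoys passes the
2-fold rule. `runAll(config)` wraps the same stages (plus annotation
and statistics) into one call that writes `peaks.tsv`,
`enrichment.tsv`, `annot.tsv`, category tables and a `manifest.json`
from which the run can be reproduced byte-identically;
`inst/scripts/crafd.R` exposes the stages as shell subcommands.

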