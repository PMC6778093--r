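---
title: "Methods: peak calling and enrichment analysis for sRNA pull-down coverage"
author: "crafdseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak calling and enrichment analysis for sRNA pull-down coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crafdseq)
```

# Overview

CRAFD-Seq experiments capture the RNA interaction partners of a bait
sRNA on beads and sequence the captured pool in duplicate next to an
empty-bead control. This package implements the downstream data
analysis: normalized strand-specific coverage in, enriched and
annotated target peaks plus summary statistics out. This vignette is
the package's own account of the model and every numerical choice in
it.

# Coverage model and normalization

A `CoverageTrack` is a dense vector of non-negative per-nucleotide
coverage for one strand of one library, 1-based and contiguous:
positions missing from the source file are zero-filled, so sums and
means are always over the whole replicon. Reverse-strand tracks are
kept in forward-strand coordinates; no operation in the package ever
emits flipped coordinates.

Normalization multiplies a raw track by `scale / totalMappedReads`
(default `scale = 1e6`, the reads-per-million convention). The
library size defaults to the raw coverage sum over both strands of
the library, so a run is self-contained without access to the
original alignments; callers who know the true mapped-read count can
pass it instead. Both definitions differ only by a per-library
constant, and every downstream decision — boundary detection, the
relative coverage filter, enrichment folds — is a ratio, so the
choice of `scale` cannot change any peak call (this scale invariance
is asserted in the test suite). Normalizing twice is an error rather
than a no-op: the flag on the track makes the pipeline state explicit.

# The peak caller

Peak boundaries are detected by comparing the mean coverage of two
`window`-nt ranges separated by a `spacer`-nt gap. With values
\(v\), window \(w\), spacer \(s\) and pseudocount \(\varepsilon\),
position \(i\) is a raw **start** candidate when

\[
\frac{\overline{v}[i, i+w-1] + \varepsilon}
     {\overline{v}[i-s-w, i-s-1] + \varepsilon} \ge f,
\]

and position \(j\) a raw **end** candidate when the window ending at
\(j\) exceeds the window starting at \(j+s+1\) likewise. Defaults are
the study settings \(w = 5\), \(s = 10\), \(f = 1.5\).

**Run collapse.** On any clean transition many consecutive positions
pass the ratio test. Each maximal run of consecutive candidates of
one kind is collapsed to the position of maximal fold; tied start
candidates collapse to the *leftmost* and tied end candidates to the
*rightmost* tied position. The asymmetry is deliberate and forced by
the geometry: on a noiseless step the maximal start fold is attained
from the first elevated base onward and the maximal end fold from the
last elevated base backward, so this mirror-image tie-break — and
only this one — reproduces the step edges exactly (a 10→20→10 step
of width 70 yields precisely one start at its first and one end at
its last elevated base). Reported peaks therefore contain only
elevated coverage.

**Pairing.** Boundaries are paired by a left-to-right scan: the first
start opens an interval, further starts before an end are interior
and ignored, the first end at or after the open start closes it;
dangling ends are dropped, and a still-open interval at the track end
is discarded unless `closeOpenPeaks` asks for closure at the last
position. This is the simplest deterministic rule consistent with
"a start and an end delimit a peak". Its known failure mode is a
spurious noise start far upstream of a real peak swallowing that
peak's end; with duplicate libraries merged before calling (the
default pipeline) the false-boundary rate at background mean 20–25 is
low enough that this affects on the order of one peak in thirty,
which the recovery statistics in the tests reflect.

**Coverage filter.** A paired interval is kept only when its mean
coverage is at least `minCovFrac` (default 0.2) of the *dataset* mean
coverage per nucleotide — by default the grand mean over both strands
of the library being called, making the filter global: a small local
peak in a library dominated by a few huge plateaus is discarded even
if its local contrast is high.

**Pseudocount.** \(\varepsilon\) (default 0.1 normalized units) caps
the fold off zero background: without it a single read next to an
empty region yields an infinite fold. On strictly positive tracks
\(\varepsilon = 0\) is valid, and under global rescaling of the
coverage \(\varepsilon\) co-scales, preserving calls exactly.

**Degenerate inputs.** Tracks shorter than \(2w + s\) yield no
candidates; windows never extend past the track ends unless
`circular = TRUE`, in which case indices wrap (for circular bacterial
chromosomes).

# Enrichment against the control

For each called peak and each pull-down replicate the fold change is
the ratio of mean normalized coverage over the peak interval
(pull-down over control, both offset by the pseudocount). The
interval *mean* — not the maximum or the sum — matches the
per-nucleotide semantics of the coverage tables. Status is three-way:
**enriched** when every replicate is *strictly more than*
`foldThreshold` (default 2.0) above control, **partially enriched**
when some but not all are, **not enriched** otherwise. The strict
inequality means a replicate at exactly 2.0-fold does not count. One
control library serves all replicates; replicate-matched controls can
be handled by repeated calls.

# Genomic categories

Features come from GFF3 (CDS, RNA genes, optional explicit UTRs;
`gene` containers only donate names and functional categories to
their children). Where explicit UTRs are absent they can be derived
as flanks (defaults 100 nt 5′, 50 nt 3′, strand-aware), clipped at
genome ends and at the nearest same-strand feature; when the derived
3′UTR of one gene and the 5′UTR of the next collide, the overlap is
split at its midpoint. Derived UTRs consequently never overlap any
same-strand feature. Flank derivation is a documented fallback for
genomes whose transcription-start maps are unavailable; analyses with
curated UTR coordinates should supply them explicitly, and category
fractions will differ between the two routes.

Each peak is assigned the single feature with maximal overlap in nt,
either strand, ties broken by kind precedence
5′UTR > 3′UTR > RNA gene > CDS, then smaller feature, then
lexicographic id. The category is the feature kind, prefixed `as`
when the strands differ — sense and antisense candidates compete on
equal footing, which matters because antisense targeting is a real
and sometimes dominant mode of sRNA regulation. Peaks overlapping
nothing are `intergenic`, a category added for closure on sparse
annotations (the distribution over categories must sum to one).

# Statistics

**Functional-category enrichment** uses the exact one-sided
hypergeometric upper tail: with `n` background genes, `K` of them in
a category, and `m` targets of which `k` are in the category, the
p-value is \(P(X \ge k)\) for
\(X \sim \mathrm{Hypergeom}(n, K, m)\). Benjamini–Hochberg adjusted
values are reported alongside the raw ones, and rows are flagged at
both raw \(p < \alpha\) (the conventional reporting filter) and
adjusted \(p < \alpha\) (recommended). Genes carrying several
categories count once in each; no down-weighting is applied.

**Rank comparison** uses the Kruskal-Wallis statistic over mid-ranks
with the standard tie correction
\(1 - \sum_t (t^3 - t)/(N^3 - N)\). With the two groups
enriched/non-enriched this is equivalent to a two-sided rank-sum
test, but the H form is kept so more than two groups work unchanged.
The p-value comes from the \(\chi^2_{k-1}\) approximation, or — when
the pooled sample has at most 10 observations — from exact
enumeration of all group assignments (at most
\(\binom{10}{5} = 252\)). Two numerical notes: (i) when every
observation is identical the tie-correction denominator vanishes and
H is defined as 0 with p = 1; (ii) the permutation null is discrete,
so the continuous \(\chi^2\) tail is best compared with the
permutation *mid-p* (half weight on assignments with H equal to the
observed value) — for balanced tie-free groups of 8 the two agree to
well under 0.02 on average, while the plain \(\ge\)-tail can differ
by up to ~0.05 in the high-p region. With one observation per group
every assignment produces the same H, so the exact p is necessarily 1
— the test is vacuous below two observations per group.

# The synthetic generator

`simulationConfig()` fixes the synthetic study conditions: a 50 kb
single replicon, 60 genes of 200–1500 nt placed without same-strand
overlap (opposite strands may overlap, as in dense bacterial
genomes; ~15% are RNA genes without UTRs), Poisson background with
mean 25 per nucleotide, 30 planted true peaks of fold 2.5–6.0 and
width 30–150 nt, 10 decoys of fold 1.0–1.4, duplicate pull-down
libraries with per-peak lognormal fold jitter (sd 0.1 on the log
scale) and unequal sequencing depths (factors 1.0 and 1.6, so
normalization has real work to do), and an unenriched control.
Planted peaks multiply the shared background expectation — the
multiplicative model mirrors affinity capture, where targets are
enriched out of the same transcriptome rather than added on top of
it, and it is what makes a fold-change rule meaningful. Decoys sit
below the boundary threshold so the partially/not-enriched branches
are exercised. A `delta` noise mode returns expectations exactly for
noiseless unit checks, and a negative-binomial mode is available for
overdispersion studies.

What the simulation does *not* emulate: transcription-unit structure
in the background (real coverage is concentrated in transcribed
regions and far from flat), positional coverage biases,
fragment-length effects, and multi-replicon genomes. Passing the
recovery tests therefore demonstrates the correctness and calibration
of the algorithms under the stated noise model, not performance on
any particular real library.

Recovery is scored by same-strand reciprocal overlap ≥ 50% between
enriched calls and planted intervals; with no calls at all precision
is reported as 1.0 with an explicit flag rather than NA, so
monitoring pipelines see a defined value.

# Problem sizes and runtime choices

The test suite verifies the caller against an exhaustive
position-by-position oracle on 500 random tracks of up to 2 kb,
the annotation classifier against a feature-enumeration oracle on
200 peaks × 50 features, the hypergeometric tail against full draw
enumeration for all backgrounds up to 12 genes, and boundary-accurate
recovery of 200 planted peaks on a 250 kb genome. These sizes give
exhaustive or near-exhaustive coverage of each rule while keeping the
whole suite in the low minutes on one core; the algorithms themselves
are linear in genome length and were exercised up to 250 kb here.

# Known limitations

- The greedy boundary pairing can merge a noise boundary with a real
  peak (see above); an interval-scoring pairer would be more robust
  but would no longer be the transparent two-boundary rule this
  package implements.
- The 2-fold enrichment rule is a threshold, not a test: no
  per-peak significance is attached, by design.
- Single replicon per run; bigWig input and read-level processing
  (mapping, deduplication) are out of scope — the pipeline starts
  from coverage.
- Derived flank UTRs are a fallback, not a substitute for measured
  transcript boundaries.
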