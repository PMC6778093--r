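Package: crafdseq
Title: Peak Calling and Enrichment Analysis for sRNA Affinity Pull-Down
    Sequencing (CRAFD-Seq)
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for cell-free RNA affinity pull-down
    sequencing (CRAFD-Seq) of small regulatory RNA targetomes. Reads,
    normalizes and merges strand-specific per-nucleotide coverage tracks
    (grp and wiggle formats), calls coverage peaks with a sliding-window
    fold-change boundary detector, classifies peaks as enriched against an
    empty-bead control library under a duplicate-replicate 2-fold rule,
    annotates peaks into genomic categories (CDS, UTRs, RNA genes and
    their antisense counterparts), and provides downstream statistics:
    hypergeometric functional-category enrichment and Kruskal-Wallis rank
    comparison of predicted interaction-site ranks. Includes a synthetic
    coverage simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: Transcriptomics, PeakDetection, Coverage, Sequencing,
    GeneRegulation, SmallRNA
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
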