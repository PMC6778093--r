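writeGffLines <- function(lines) {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), p)
  p
}

test_that("GFF3 records map onto feature kinds", {
  p <- writeGffLines(c(
    "chr\tsrc\tCDS\t101\t400\t.\t+\t.\tID=cds1;category=translation",
    "chr\tsrc\tncRNA\t500\t560\t.\t-\t.\tID=rna1",
    "chr\tsrc\tfive_prime_UTR\t81\t100\t.\t+\t.\tID=u5;Parent=cds1",
    "chr\tsrc\tregion\t1\t1000\t.\t+\t.\tID=reg"
  ))
  expect_message(fs <- readGff(p, 1000), "skipped 1")
  expect_equal(length(fs), 3L)
  mc <- S4Vectors::mcols(fs)
  expect_setequal(mc$kind, c("CDS", "RNA_gene", "five_prime_UTR"))
  expect_equal(mc$functional_category[mc$feature_id == "cds1"], "translation")
  expect_equal(mc$parent_id[mc$feature_id == "u5"], "cds1")
})

test_that("features beyond the genome end are a coordinate error", {
  p <- writeGffLines(
    "chr\tsrc\tCDS\t999900\t1000001\t.\t+\t.\tID=cds1"
  )
  expect_error(readGff(p, 1000000), class = "crafd_coordinate_error")
})

test_that("gene containers pass their name and category to children", {
  p <- writeGffLines(c(
    "chr\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1;Name=glgC;category=energy",
    "chr\tsrc\tCDS\t101\t400\t.\t+\t.\tID=g1.cds;Parent=g1"
  ))
  fs <- readGff(p, 1000)
  mc <- S4Vectors::mcols(fs)
  expect_equal(length(fs), 1L)
  expect_equal(mc$gene_name, "glgC")
  expect_equal(mc$functional_category, "energy")
  expect_equal(mc$parent_id, "g1")
})

test_that("flank UTRs are derived strand-aware and clipped at genome ends", {
  p <- writeGffLines(
    "chr\tsrc\tCDS\t201\t400\t.\t+\t.\tID=cds1"
  )
  fs <- deriveUtrs(readGff(p, 1000))
  mc <- S4Vectors::mcols(fs)
  u5 <- fs[mc$kind == "five_prime_UTR"]
  u3 <- fs[mc$kind == "three_prime_UTR"]
  expect_equal(c(BiocGenerics::start(u5), BiocGenerics::end(u5)), c(101L, 200L))
  expect_equal(c(BiocGenerics::start(u3), BiocGenerics::end(u3)), c(401L, 450L))
  # minus strand mirrors
  p <- writeGffLines(
    "chr\tsrc\tCDS\t201\t400\t.\t-\t.\tID=cds1"
  )
  fs <- deriveUtrs(readGff(p, 1000))
  mc <- S4Vectors::mcols(fs)
  u5 <- fs[mc$kind == "five_prime_UTR"]
  u3 <- fs[mc$kind == "three_prime_UTR"]
  expect_equal(c(BiocGenerics::start(u5), BiocGenerics::end(u5)), c(401L, 500L))
  expect_equal(c(BiocGenerics::start(u3), BiocGenerics::end(u3)), c(151L, 200L))
  # genome-end clipping
  p <- writeGffLines(
    "chr\tsrc\tCDS\t50\t120\t.\t+\t.\tID=cds1"
  )
  fs <- deriveUtrs(readGff(p, 140))
  mc <- S4Vectors::mcols(fs)
  expect_equal(BiocGenerics::start(fs[mc$kind == "five_prime_UTR"]), 1L)
  expect_equal(BiocGenerics::end(fs[mc$kind == "three_prime_UTR"]), 140L)
})

test_that("colliding derived UTRs split at the midpoint of the gap", {
  p <- writeGffLines(c(
    "chr\tsrc\tCDS\t201\t400\t.\t+\t.\tID=cds1",
    "chr\tsrc\tCDS\t451\t700\t.\t+\t.\tID=cds2"
  ))
  fs <- deriveUtrs(readGff(p, 1000))
  mc <- S4Vectors::mcols(fs)
  u3a <- fs[mc$feature_id == "cds1.3utr"]
  u5b <- fs[mc$feature_id == "cds2.5utr"]
  expect_equal(
    c(BiocGenerics::start(u3a), BiocGenerics::end(u3a)), c(401L, 425L)
  )
  expect_equal(
    c(BiocGenerics::start(u5b), BiocGenerics::end(u5b)), c(426L, 450L)
  )
})

test_that("explicit UTRs suppress derivation for their side", {
  p <- writeGffLines(c(
    "chr\tsrc\tCDS\t201\t400\t.\t+\t.\tID=cds1",
    "chr\tsrc\tfive_prime_UTR\t190\t200\t.\t+\t.\tID=u5;Parent=cds1"
  ))
  fs <- deriveUtrs(readGff(p, 1000))
  mc <- S4Vectors::mcols(fs)
  expect_equal(sum(mc$kind == "five_prime_UTR"), 1L) # the explicit one
  expect_equal(BiocGenerics::start(fs[mc$kind == "five_prime_UTR"]), 190L)
  expect_equal(sum(mc$kind == "three_prime_UTR"), 1L) # derived
})

test_that("derived UTRs never overlap same-strand features", {
  set.seed(303)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    starts <- sort(sample(seq(1, 4500, by = 10), n))
    features <- data.frame(
      feature_id = sprintf("c%02d", seq_len(n)),
      kind = "CDS",
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = starts,
      end = pmin(5000, starts + sample(50:400, n, replace = TRUE))
    )
    features <- features[c(TRUE, features$start[-1] > features$end[-n]), ]
    fs <- deriveUtrs(featuresToGRanges(features, 5000))
    mc <- S4Vectors::mcols(fs)
    derived <- grepl("utr$", mc$feature_id)
    for (sd in c("+", "-")) {
      dIdx <- which(derived & as.character(BiocGenerics::strand(fs)) == sd)
      oIdx <- which(as.character(BiocGenerics::strand(fs)) == sd)
      for (i in dIdx) {
        for (j in setdiff(oIdx, i)) {
          ov <- min(BiocGenerics::end(fs)[i], BiocGenerics::end(fs)[j]) -
            max(BiocGenerics::start(fs)[i], BiocGenerics::start(fs)[j]) + 1
          expect_lte(ov, 0)
        }
      }
      expect_true(all(BiocGenerics::start(fs)[dIdx] >= 1))
      expect_true(all(BiocGenerics::end(fs)[dIdx] <= 5000))
    }
  }
})

test_that("peaks classify by maximal overlap with antisense prefixing", {
  features <- data.frame(
    feature_id = c("u5a", "cds1"),
    kind = c("five_prime_UTR", "CDS"),
    strand = c("+", "+"),
    start = c(81, 101), end = c(100, 400)
  )
  fs <- featuresToGRanges(features, 1000)
  classify <- function(s, e, sd) {
    pk <- GenomicRanges::GRanges(
      "genome", IRanges::IRanges(s, e), strand = sd
    )
    S4Vectors::mcols(annotatePeaks(pk, fs))$category
  }
  expect_equal(classify(150, 180, "+"), "CDS")
  expect_equal(classify(150, 180, "-"), "asCDS")
  # 6 nt of 5'UTR vs 30 nt of CDS: majority overlap wins
  expect_equal(classify(95, 130, "+"), "CDS")
  expect_equal(classify(500, 600, "+"), "intergenic")
})

test_that("classifier agrees with the brute-force overlap oracle", {
  set.seed(404)
  kinds <- c("CDS", "RNA_gene", "five_prime_UTR", "three_prime_UTR")
  nFeat <- 50
  starts <- sample(3000, nFeat)
  features <- data.frame(
    feature_id = sprintf("f%02d", seq_len(nFeat)),
    kind = sample(kinds, nFeat, replace = TRUE),
    strand = sample(c("+", "-"), nFeat, replace = TRUE),
    start = starts,
    end = pmin(3200, starts + sample(20:300, nFeat, replace = TRUE))
  )
  fs <- featuresToGRanges(features, 3200)
  nPeaks <- 200
  ps <- sample(3100, nPeaks)
  pe <- pmin(3200, ps + sample(10:120, nPeaks, replace = TRUE))
  pstr <- sample(c("+", "-"), nPeaks, replace = TRUE)
  pk <- GenomicRanges::GRanges(
    rep("genome", nPeaks), IRanges::IRanges(ps, pe), strand = pstr
  )
  got <- S4Vectors::mcols(annotatePeaks(pk, fs))$category
  ref <- vapply(seq_len(nPeaks), function(i) {
    bfClassifyPeak(ps[i], pe[i], pstr[i], features)
  }, character(1))
  expect_equal(got, ref)
})

test_that("peaks collapse to unique genes, antisense separately", {
  features <- data.frame(
    feature_id = c("g1.5utr", "g1", "g1.3utr", "g2"),
    kind = c("five_prime_UTR", "CDS", "three_prime_UTR", "CDS"),
    strand = "+",
    start = c(101, 201, 501, 701), end = c(200, 500, 550, 900)
  )
  fs <- featuresToGRanges(features, 1000)
  S4Vectors::mcols(fs)$parent_id <- c("g1", "g1", "g1", "g2")
  pk <- GenomicRanges::GRanges(
    rep("genome", 4),
    IRanges::IRanges(c(110, 300, 510, 750), c(150, 340, 540, 800)),
    strand = c("+", "+", "+", "-")
  )
  S4Vectors::mcols(pk)$peak_id <- 1:4
  ann <- annotatePeaks(pk, fs)
  genes <- peaksToGenes(ann)
  expect_equal(genes$sense$gene_id, "g1")
  expect_equal(genes$sense$n_peaks, 3L)
  expect_equal(sort(genes$sense$peak_ids[[1]]), 1:3)
  expect_equal(genes$antisense$gene_id, "g2")
  # unique gene count never exceeds peak count
  expect_lte(
    nrow(genes$sense) + nrow(genes$antisense), length(pk)
  )
  empty <- peaksToGenes(ann[0])
  expect_equal(nrow(empty$sense), 0L)
})

test_that("category distribution is a probability vector over categories", {
  pk <- GenomicRanges::GRanges(
    rep("genome", 4),
    IRanges::IRanges(c(1, 11, 21, 31), c(5, 15, 25, 35)),
    strand = "+"
  )
  S4Vectors::mcols(pk)$category <- c("CDS", "CDS", "asCDS", "5UTR")
  d <- categoryDistribution(pk)
  expect_equal(unname(d["CDS"]), 0.5)
  expect_equal(unname(d["asCDS"]), 0.25)
  expect_equal(unname(d["5UTR"]), 0.25)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  # permutation invariance
  expect_equal(categoryDistribution(pk[c(3, 1, 4, 2)]), d)
  # all intergenic
  S4Vectors::mcols(pk)$category <- rep("intergenic", 4)
  expect_equal(unname(categoryDistribution(pk)["intergenic"]), 1)
  expect_error(categoryDistribution(pk[0]), class = "crafd_domain_error")
})
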