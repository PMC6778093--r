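stepTrack <- function() {
  CoverageTrack(
    c(rep(10, 50), rep(20, 70), rep(10, 80)), "F",
    label = "step", normalized = TRUE
  )
}

test_that("flat coverage yields no boundary candidates", {
  tr <- CoverageTrack(rep(10, 200), "F", normalized = TRUE)
  expect_equal(nrow(scanBoundaries(tr)), 0L)
})

test_that("a clean step yields one start and one end at the step edges", {
  b <- scanBoundaries(stepTrack())
  expect_equal(b$position[b$kind == "start"], 51)
  expect_equal(b$position[b$kind == "end"], 120)
  expect_equal(
    b$fold[b$kind == "start"], (20 + 0.1) / (10 + 0.1),
    tolerance = 1e-12
  )
})

test_that("sub-threshold steps are rejected at the 1.5-fold boundary rule", {
  tr <- CoverageTrack(
    c(rep(10, 50), rep(14, 70), rep(10, 80)), "F", normalized = TRUE
  )
  expect_equal(nrow(scanBoundaries(tr)), 0L)
  expect_length(callPeaks(tr), 0L)
})

test_that("tracks shorter than the window geometry yield nothing", {
  tr <- CoverageTrack(c(0, 100, 0), "F")
  expect_equal(nrow(scanBoundaries(tr)), 0L)
})

test_that("boundary pairing follows the greedy left-to-right scan", {
  p <- peakCallParams()
  mk <- function(starts, ends) {
    rbind(
      data.frame(
        position = starts, kind = rep("start", length(starts)),
        fold = rep(2, length(starts))
      ),
      data.frame(
        position = ends, kind = rep("end", length(ends)),
        fold = rep(2, length(ends))
      )
    )
  }
  iv <- pairBoundaries(mk(100, 200), 500, p)
  expect_equal(as.data.frame(iv)[, c("start", "end")],
    data.frame(start = 100L, end = 200L))
  # interior second start is ignored
  iv <- pairBoundaries(mk(c(100, 150), 200), 500, p)
  expect_equal(length(iv), 1L)
  expect_equal(BiocGenerics::start(iv), 100L)
  # unmatched open start discarded by default, closed at track end on demand
  expect_length(pairBoundaries(mk(100, integer(0)), 500, p), 0L)
  pOpen <- peakCallParams(closeOpenPeaks = TRUE)
  iv <- pairBoundaries(mk(100, integer(0)), 500, pOpen)
  expect_equal(BiocGenerics::end(iv), 500L)
  # ends with no open interval are ignored
  expect_length(pairBoundaries(mk(integer(0), 90), 500, p), 0L)
})

test_that("dataset mean coverage is the grand mean over all tracks", {
  f <- CoverageTrack(c(0, 10), "F")
  r <- CoverageTrack(c(10, 20), "R")
  expect_equal(datasetMeanCoverage(list(f, r)), 10)
  expect_equal(datasetMeanCoverage(list(r, f)), 10)
  expect_equal(datasetMeanCoverage(list(CoverageTrack(c(0, 0), "F"))), 0)
  expect_error(datasetMeanCoverage(list()), class = "crafd_domain_error")
})

test_that("the step peak survives the 20% coverage filter end to end", {
  peaks <- callPeaks(stepTrack())
  expect_length(peaks, 1L)
  expect_equal(BiocGenerics::start(peaks), 51L)
  expect_equal(BiocGenerics::end(peaks), 120L)
  expect_equal(S4Vectors::mcols(peaks)$mean_coverage, 20)
  # dataset mean 13.5 -> threshold 2.7 <= 20
  expect_equal(datasetMeanCoverage(list(stepTrack())), 13.5)
})

test_that("the coverage filter is global: a distant plateau removes a low peak", {
  # small 2x peak over background 1, plus a huge plateau elsewhere in the
  # dataset (companion strand) that lifts the dataset mean
  v <- c(rep(1, 100), rep(2.5, 50), rep(1, 100))
  tr <- CoverageTrack(v, "F", normalized = TRUE)
  companion <- CoverageTrack(rep(100, 250), "R", normalized = TRUE)
  alone <- callPeaks(tr, params = peakCallParams(pseudocount = 0))
  expect_length(alone, 1L) # local call succeeds without the plateau
  withPlateau <- callPeaks(tr, list(companion),
    params = peakCallParams(pseudocount = 0)
  )
  expect_length(withPlateau, 0L) # 2.5 < 0.2 * dataset mean
})

test_that("peak calls are invariant under coverage rescaling", {
  set.seed(33)
  base <- randomTrack(1500)
  for (k in c(0.01, 1, 1000)) {
    tr <- CoverageTrack(base * k, "F", normalized = TRUE)
    p <- peakCallParams(pseudocount = 0.1 * k)
    got <- callPeaks(tr, params = p)
    ref <- callPeaks(CoverageTrack(base, "F", normalized = TRUE),
      params = peakCallParams(pseudocount = 0.1)
    )
    expect_equal(BiocGenerics::start(got), BiocGenerics::start(ref))
    expect_equal(BiocGenerics::end(got), BiocGenerics::end(ref))
  }
})

test_that("raising fold or coverage thresholds never adds peaks", {
  set.seed(12)
  for (rep in 1:10) {
    v <- randomTrack(800)
    tr <- CoverageTrack(v, "F", normalized = TRUE)
    base <- length(callPeaks(tr, params = peakCallParams()))
    expect_lte(
      length(callPeaks(tr, params = peakCallParams(fold = 2))), base
    )
    expect_lte(
      length(callPeaks(tr, params = peakCallParams(minCovFrac = 0.5))), base
    )
  }
})

test_that("per-strand peaks are disjoint and sorted", {
  set.seed(99)
  for (rep in 1:10) {
    tr <- CoverageTrack(randomTrack(1000), "F", normalized = TRUE)
    p <- callPeaks(tr)
    if (length(p) > 1) {
      st <- BiocGenerics::start(p)
      en <- BiocGenerics::end(p)
      expect_true(all(diff(st) > 0))
      expect_true(all(st[-1] > en[-length(en)]))
    }
  }
})

test_that("vectorized caller equals the brute-force oracle on random tracks", {
  set.seed(4711)
  for (rep in 1:60) {
    len <- sample(40:2000, 1)
    v <- randomTrack(len)
    tr <- CoverageTrack(v, "F", normalized = TRUE)
    got <- callPeaks(tr)
    ref <- bfCallPeaks(v)
    expect_equal(length(got), nrow(ref))
    if (length(got)) {
      expect_equal(BiocGenerics::start(got), as.integer(ref[, 1]))
      expect_equal(BiocGenerics::end(got), as.integer(ref[, 2]))
      expect_equal(S4Vectors::mcols(got)$mean_coverage, unname(ref[, 3]))
    }
  }
})

test_that("boundary scan equals the oracle for non-default window geometry", {
  set.seed(8)
  for (rep in 1:10) {
    v <- randomTrack(400)
    w <- sample(2:8, 1)
    s <- sample(0:12, 1)
    f <- stats::runif(1, 1.2, 2.5)
    tr <- CoverageTrack(v, "F", normalized = TRUE)
    got <- scanBoundaries(tr, peakCallParams(window = w, spacer = s, fold = f))
    ref <- bfScanBoundaries(v, w, s, f, 0.1)
    expect_equal(
      got$position[got$kind == "start"], ref$starts$position
    )
    expect_equal(got$position[got$kind == "end"], ref$ends$position)
  }
})

test_that("planted peaks are recovered with tight boundaries", {
  # 200 planted peaks, fold >= 2, width >= 30 nt, Poisson background
  # mean 20; boundaries must land within spacer + window of the truth
  cfg <- simulationConfig(
    genomeLength = 250000L, nGenes = 120L, nTruePeaks = 200L,
    trueFoldRange = c(2, 6), nDecoyPeaks = 0L, backgroundMean = 20,
    peakWidthRange = c(30L, 150L), replicateJitterSd = 0,
    nReplicates = 2L, depthFactors = 1, seed = 2024L
  )
  fs <- simulateAnnotation(cfg)
  sim <- simulateLibraries(cfg, fs)
  reps <- lapply(sim$pulldown, normPair)
  merged <- list(
    fwd = mergeTracks(lapply(reps, `[[`, "fwd")),
    rev = mergeTracks(lapply(reps, `[[`, "rev"))
  )
  pk <- callPeaksBothStrands(merged$fwd, merged$rev)
  tol <- 10 + 5 # spacer + window
  truth <- sim$truth
  okBoth <- logical(nrow(truth))
  st <- BiocGenerics::start(pk)
  en <- BiocGenerics::end(pk)
  sd_ <- as.character(BiocGenerics::strand(pk))
  for (i in seq_len(nrow(truth))) {
    sel <- sd_ == truth$strand[i]
    okBoth[i] <- any(
      sel & abs(st - truth$start[i]) <= tol & abs(en - truth$end[i]) <= tol
    )
  }
  expect_gte(mean(okBoth), 0.95)
})
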