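#' Functional-category enrichment of target genes
#'
#' For each functional category, tests whether the target gene set is
#' over-represented relative to the background using the exact one-sided
#' hypergeometric upper tail: the probability of drawing at least
#' `k_targets_in_cat` category members when `n_targets` genes are drawn
#' from a background of `n_background` genes of which
#' `k_background_in_cat` belong to the category. Benjamini-Hochberg
#' adjusted p-values are reported alongside; a gene carrying several
#' categories counts once in each.
#'
#' @param targetGenes character vector of target gene ids (must all occur
#'   in the background).
#' @param backgroundCategories named list: gene id -> character vector of
#'   functional categories (possibly empty).
#' @param alpha significance level used for the `significant_raw` /
#'   `significant_adj` flags (default 0.05).
#' @return A `data.frame` with one row per category: `category`,
#'   `n_background`, `k_background_in_cat`, `n_targets`,
#'   `k_targets_in_cat`, `p_value`, `adjusted_p`, `significant_raw`,
#'   `significant_adj`, sorted by `p_value`.
#' @examples
#' bg <- c(
#'   setNames(rep(list("C"), 5), paste0("g", 1:5)),
#'   setNames(rep(list("D"), 5), paste0("g", 6:10))
#' )
#' categoryEnrichment(paste0("g", 1:4), bg)
#' @export
categoryEnrichment <- function(targetGenes, backgroundCategories,
                               alpha = 0.05) {
  targetGenes <- unique(as.character(targetGenes))
  bgGenes <- names(backgroundCategories)
  if (is.null(bgGenes) || anyDuplicated(bgGenes)) {
    stopDomain("'backgroundCategories' must be a uniquely named list")
  }
  missing_ <- setdiff(targetGenes, bgGenes)
  if (length(missing_)) {
    stopDomain(
      "target gene(s) absent from background: ",
      paste(utils::head(missing_, 5), collapse = ", ")
    )
  }
  cats <- sort(unique(unlist(backgroundCategories, use.names = FALSE)))
  n <- length(bgGenes)
  m <- length(targetGenes)
  rows <- lapply(cats, function(cat) {
    inCat <- vapply(
      backgroundCategories, function(cc) cat %in% cc, logical(1)
    )
    K <- sum(inCat)
    k <- sum(targetGenes %in% bgGenes[inCat])
    p <- stats::phyper(k - 1, K, n - K, m, lower.tail = FALSE)
    data.frame(
      category = cat, n_background = n, k_background_in_cat = K,
      n_targets = m, k_targets_in_cat = k, p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      category = character(0), n_background = integer(0),
      k_background_in_cat = integer(0), n_targets = integer(0),
      k_targets_in_cat = integer(0), p_value = numeric(0)
    )
  }
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant_raw <- out$p_value < alpha
  out$significant_adj <- out$adjusted_p < alpha
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# H statistic with mid-ranks and tie correction
kwStatistic <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Rg <- vapply(seq_along(groups), function(g) {
    sum(r[starts[g]:ends[g]])
  }, numeric(1))
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / sizes) - 3 * (N + 1)
  tie <- table(x)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (corr == 0) return(0) # every observation identical
  H / corr
}

#' Kruskal-Wallis rank test
#'
#' Computes the Kruskal-Wallis H statistic over mid-ranks of the pooled
#' sample, with the standard tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`. The p-value comes from the chi-square
#' approximation with `k - 1` degrees of freedom, or from exact
#' enumeration of all group-label assignments when the pooled sample size
#' is at most `exactLimit` (`method = "auto"`).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param method `"auto"` (exact when `N <= exactLimit`),
#'   `"chi_square"`, or `"exact_permutation"`.
#' @param exactLimit pooled-size cutoff for the exact path (default 10,
#'   at most `choose(10, 5) = 252` assignments for two groups).
#' @return A list of class `RankComparison`: `H`, `p_value`, `method`
#'   (the method actually used), `ranks` (per-group mid-ranks) and
#'   `group_sizes`.
#' @examples
#' kruskalWallisRank(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
kruskalWallisRank <- function(groups,
                              method = c("auto", "chi_square",
                                         "exact_permutation"),
                              exactLimit = 10L) {
  method <- match.arg(method)
  if (length(groups) < 2L) stopDomain("need at least two groups")
  if (any(lengths(groups) == 0L)) stopDomain("empty group")
  groups <- lapply(groups, as.numeric)
  N <- sum(lengths(groups))
  if (method == "auto") {
    method <- if (N <= exactLimit) "exact_permutation" else "chi_square"
  }
  H <- kwStatistic(groups)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  sizes <- lengths(groups)
  if (method == "chi_square") {
    p <- stats::pchisq(H, df = k - 1L, lower.tail = FALSE)
  } else {
    p <- exactKwPvalue(x, sizes, H)
  }
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ranks <- lapply(seq_len(k), function(g) r[starts[g]:ends[g]])
  structure(
    list(
      H = H, p_value = p, method = method, ranks = ranks,
      group_sizes = sizes
    ),
    class = "RankComparison"
  )
}

# exact permutation p: enumerate all distinct assignments of the pooled
# observations to groups of the given sizes and count H >= observed
exactKwPvalue <- function(x, sizes, Hobs) {
  N <- length(x)
  assignments <- enumerateAssignments(seq_len(N), sizes)
  Hs <- vapply(assignments, function(ix) {
    kwStatistic(lapply(ix, function(i) x[i]))
  }, numeric(1))
  mean(Hs >= Hobs - 1e-12)
}

# all ways to split `idx` into ordered groups of the given sizes
enumerateAssignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(list(idx)))
  picks <- utils::combn(length(idx), sizes[1L], simplify = FALSE)
  out <- list()
  for (p in picks) {
    rest <- enumerateAssignments(idx[-p], sizes[-1L])
    for (r in rest) {
      out[[length(out) + 1L]] <- c(list(idx[p]), r)
    }
  }
  out
}

#' @export
print.RankComparison <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis rank comparison: H = %.4g, p = %.4g (%s), groups n = %s\n",
    x$H, x$p_value, x$method, paste(x$group_sizes, collapse = "/")
  ))
  if (!is.null(x$medians)) {
    cat(sprintf(
      "  median rank enriched = %g, non-enriched = %g; direction: %s\n",
      x$medians[["enriched"]], x$medians[["not_enriched"]], x$direction
    ))
  }
  invisible(x)
}

#' Compare predicted interaction-site ranks of enriched vs non-enriched peaks
#'
#' Runs the Kruskal-Wallis rank test on the whole-genome interaction
#' prediction ranks (e.g. intaRNA ranks; lower = stronger predicted
#' interaction) of enriched versus non-enriched peaks. Partially enriched
#' peaks are excluded by default.
#'
#' @param peakTable a `data.frame` with a numeric `rank` column and
#'   either a `status` column (levels as in [classifyPeaks()]) or a
#'   logical `enriched` column.
#' @param includePartial count partially enriched peaks as enriched
#'   instead of dropping them?
#' @param method passed to [kruskalWallisRank()].
#' @return A `RankComparison` with additional elements `medians` (median
#'   rank per group) and `direction` (`"enriched-better"` when the
#'   enriched group has the smaller median rank, `"non-enriched-better"`
#'   otherwise, `"tied"` on equality).
#' @export
compareEnrichedRanks <- function(peakTable, includePartial = FALSE,
                                 method = "auto") {
  if (!is.data.frame(peakTable) || !"rank" %in% names(peakTable)) {
    stopDomain("'peakTable' must be a data.frame with a 'rank' column")
  }
  if ("status" %in% names(peakTable)) {
    st <- as.character(peakTable$status)
    keep <- st %in% c("enriched", "not_enriched") |
      (includePartial & st == "partially_enriched")
    tab <- peakTable[keep, , drop = FALSE]
    isEnr <- as.character(tab$status) != "not_enriched"
  } else if ("enriched" %in% names(peakTable)) {
    tab <- peakTable
    isEnr <- as.logical(tab$enriched)
  } else {
    stopDomain("'peakTable' needs a 'status' or 'enriched' column")
  }
  ok <- !is.na(tab$rank) & !is.na(isEnr)
  tab <- tab[ok, , drop = FALSE]
  isEnr <- isEnr[ok]
  rE <- tab$rank[isEnr]
  rN <- tab$rank[!isEnr]
  if (!length(rE) || !length(rN)) {
    stopDomain("both an enriched and a non-enriched group are required")
  }
  res <- kruskalWallisRank(list(rE, rN), method = method)
  res$medians <- c(
    enriched = stats::median(rE), not_enriched = stats::median(rN)
  )
  res$direction <- if (res$medians[1L] < res$medians[2L]) {
    "enriched-better"
  } else if (res$medians[1L] > res$medians[2L]) {
    "non-enriched-better"
  } else {
    "tied"
  }
  res
}
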