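#' Build a ranked gene list
#'
#' Sorts genes by their ranking statistic, descending, with deterministic
#' tie-breaking by gene name (ascending), so identical inputs always yield
#' the identical ranking regardless of input order.
#'
#' @param genes character vector of gene names.
#' @param stats numeric vector of ranking statistics, same length.
#' @return list with `genes` and `stats`, sorted.
#' @export
rankedList <- function(genes, stats) {
  stopifnot(length(genes) == length(stats), !anyNA(stats))
  ord <- order(-stats, genes)
  list(genes = genes[ord], stats = stats[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Classic GSEA running-sum statistic on a ranked list: walking down the
#' ranking, a gene in the set increments the sum by
#' `|stat|^weightExponent / sum over the set of |stat|^weightExponent`, a
#' gene outside it decrements by `1 / (N - k)`. The enrichment score is the
#' maximum positive deviation of the running sum, clipped to \[0, 1\]. A set
#' whose members cluster at the top of the ranking (similar, large
#' statistics) scores close to 1.
#'
#' @param ranked ranked list from [rankedList()].
#' @param geneset character vector of set member names.
#' @param weightExponent weighting exponent (default 1; 0 makes the score
#'   rank-only).
#' @return scalar in \[0, 1\].
#' @export
enrichmentScore <- function(ranked, geneset, weightExponent = 1) {
  hits <- which(ranked$genes %in% geneset)
  if (length(hits) == 0L)
    stop("set unmeasured: no gene of the set is in the ranked list",
         call. = FALSE)
  .esAtPositions(ranked$stats, hits, weightExponent)
}

# Running-sum maximum for hit positions `pos` (sorted ascending) on a
# descending stats vector. The maximum of the running sum is attained
# immediately after a hit, so only those points are evaluated.
.esAtPositions <- function(stats, pos, weightExponent = 1) {
  N <- length(stats)
  k <- length(pos)
  w <- abs(stats[pos])^weightExponent
  tot <- sum(w)
  hitCum <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  missPenalty <- if (N > k) (pos - seq_len(k)) / (N - k) else rep(0, k)
  es <- max(hitCum - missPenalty)
  min(max(es, 0), 1)
}

#' Gene-label permutation P-value for an enrichment score
#'
#' Compares the observed enrichment score of a gene set against the null
#' distribution of scores of random gene sets of the same size drawn
#' uniformly from the ranked list (gene-label permutation). The estimate
#' uses the plus-one correction `(b + 1) / (nPerm + 1)` where `b` counts
#' null scores >= the observed one, so p is never exactly 0. With
#' `exhaustive = TRUE` and `choose(N, k) <= exhaustiveThreshold` all sets
#' are enumerated instead and p = `(b + 1) / (nSets + 1)`.
#'
#' @param ranked ranked list from [rankedList()].
#' @param geneset character vector of set member names (at least one must
#'   be in the ranked list).
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed; fixed seed and inputs give identical p.
#' @param weightExponent see [enrichmentScore()].
#' @param exhaustive enumerate all sets when feasible.
#' @param exhaustiveThreshold feasibility cap on `choose(N, k)`.
#' @return scalar P-value in (0, 1\].
#' @export
permutationPValue <- function(ranked, geneset, nPerm = 10000L, seed = 1L,
                              weightExponent = 1, exhaustive = FALSE,
                              exhaustiveThreshold = 1e5) {
  stopifnot(nPerm >= 1L)
  N <- length(ranked$stats)
  pos <- which(ranked$genes %in% geneset)
  k <- length(pos)
  if (k == 0L)
    stop("set unmeasured: no gene of the set is in the ranked list",
         call. = FALSE)
  obs <- .esAtPositions(ranked$stats, pos, weightExponent)
  if (exhaustive && choose(N, k) <= exhaustiveThreshold) {
    sets <- utils::combn(N, k)
    null <- apply(sets, 2L, function(p)
      .esAtPositions(ranked$stats, p, weightExponent))
    b <- sum(null >= obs - 1e-12)
    return((b + 1) / (length(null) + 1))
  }
  null <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      .esAtPositions(ranked$stats, sort(sample.int(N, k)), weightExponent)
    }, numeric(1))
  })
  (sum(null >= obs - 1e-12) + 1) / (nPerm + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate across a batch
#' of tests; adjusted values are monotone in the raw P-values, never
#' smaller than them and capped at 1. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted P-values in the input order.
#' @export
bhAdjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("P-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' P-value quantile classes
#'
#' Regulons are ranked by ascending adjusted P-value (ties broken by name)
#' and divided into five classes: the 10% with the lowest values (class 1),
#' then the 10%-20%, 20%-33% and 33%-50% fractions (classes 2-4), and the
#' remaining half (class 5). Boundaries use ceiling ranks, so the classes
#' partition ranks 1..N for every N.
#'
#' @param padj numeric vector of adjusted P-values.
#' @param names character vector used for deterministic tie-breaking.
#' @return integer vector of classes 1-5, in input order.
#' @export
pvalueQuantileClass <- function(padj, names = as.character(seq_along(padj))) {
  N <- length(padj)
  if (N == 0L) return(integer(0))
  rank <- integer(N)
  rank[order(padj, names)] <- seq_len(N)
  cls <- rep.int(5L, N)
  cls[rank <= ceiling(0.50 * N)] <- 4L
  cls[rank <= ceiling(0.33 * N)] <- 3L
  cls[rank <= ceiling(0.20 * N)] <- 2L
  cls[rank <= ceiling(0.10 * N)] <- 1L
  cls
}

#' Logical-fraction classes
#'
#' Five reliability classes on the logical-regulation fraction: class 1 for
#' fractions in \[0.90, 1\], 2 for \[0.80, 0.90), 3 for \[0.75, 0.80),
#' 4 for \[0.67, 0.75) and 5 for \[0.50, 0.67); boundaries are
#' lower-inclusive. Fractions below 0.5 (which cannot arise from a
#' majority-group analysis) return `NA`.
#'
#' @param fraction numeric vector in \[0.5, 1\].
#' @return integer vector of classes 1-5 (or `NA`), in input order.
#' @export
fractionClass <- function(fraction) {
  cls <- rep.int(NA_integer_, length(fraction))
  cls[fraction >= 0.50] <- 5L
  cls[fraction >= 0.67] <- 4L
  cls[fraction >= 0.75] <- 3L
  cls[fraction >= 0.80] <- 2L
  cls[fraction >= 0.90] <- 1L
  cls
}
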