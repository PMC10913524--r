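#' Signed contribution of a gene to regulator activity
#'
#' A gene's log2 fold change, sign-flipped when the regulator represses it,
#' so that positive values always support "regulator activated" and negative
#' values "regulator repressed". E.g. a repressed target that is
#' downregulated 2.03-fold (log2FC = -2.03) contributes +2.03: its
#' downregulation is exactly what an *active* repressor produces.
#'
#' @param log2fc numeric vector of log2 fold changes (finite).
#' @param mode character vector, `"up"` (activation-type link) or `"down"`
#'   (repression-type link); recycled against `log2fc`.
#' @return numeric vector of contributions.
#' @examples
#' signedContribution(-2.03, "down")  # +2.03
#' @export
signedContribution <- function(log2fc, mode) {
  stopifnot(all(is.finite(log2fc)), all(mode %in% c("up", "down")))
  ifelse(mode == "down", -log2fc, log2fc)
}

#' Median absolute deviation of fold changes
#'
#' `median(|x - median(x)|)`, with no consistency scaling constant: the
#' statistic is used as a robust descriptive dispersion of within-set fold
#' changes, not as a sigma estimate.
#'
#' @param x numeric vector (length >= 1).
#' @return non-negative scalar.
#' @export
madFC <- function(x) {
  if (length(x) < 1L) stop("madFC: empty input", call. = FALSE)
  stats::mad(x, constant = 1)
}

#' Split a regulon into direction-consistent groups
#'
#' Computes the signed contribution of every measured regulon gene and
#' partitions genes into the group consistent with an activated regulator
#' (contribution > 0), the group consistent with a repressed regulator
#' (contribution < 0), and the uninformative zero set. Genes absent from
#' the DE table are excluded and listed under `unmatched`.
#'
#' @param links data.frame of links for one regulator (columns `gene`,
#'   `mode`), e.g. one regulator's rows of [regulonLinks()].
#' @param de DE table from [readDETable()].
#' @return list with data.frames `active` and `repressed` (columns `gene`,
#'   `log2fc`, `mode`, `contribution`), character vectors `zero` and
#'   `unmatched`, and `n_measured`.
#' @export
splitRegulon <- function(links, de) {
  stopifnot(all(c("gene", "mode") %in% names(links)))
  idx <- .matchGenes(links$gene, de)
  unmatched <- links$gene[is.na(idx)]
  links <- links[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  contrib <- signedContribution(de$log2fc[idx], links$mode)
  gc <- data.frame(gene = de$gene[idx], log2fc = de$log2fc[idx],
                   mode = links$mode, contribution = contrib,
                   stringsAsFactors = FALSE)
  list(active = gc[gc$contribution > 0, , drop = FALSE],
       repressed = gc[gc$contribution < 0, , drop = FALSE],
       zero = gc$gene[gc$contribution == 0],
       unmatched = unmatched,
       n_measured = nrow(gc))
}

#' Choose the majority group
#'
#' The larger of the two direction-consistent groups is taken as the most
#' plausible regulation situation. On equal sizes the group with the higher
#' mean absolute contribution wins (comparing signed means across two
#' oppositely-signed groups would be ill-defined); if that also ties, the
#' direction is flagged `"ambiguous"` and the activated-consistent group is
#' reported.
#'
#' @param split result of [splitRegulon()].
#' @return list with `direction` (`"activated"`, `"repressed"` or
#'   `"ambiguous"`) and `chosen` (the chosen group's data.frame).
#' @export
chooseGroup <- function(split) {
  a <- split$active
  r <- split$repressed
  if (nrow(a) == 0L && nrow(r) == 0L)
    stop("no informative genes: all contributions are zero or unmeasured",
         call. = FALSE)
  if (nrow(a) != nrow(r)) {
    if (nrow(a) > nrow(r)) list(direction = "activated", chosen = a)
    else list(direction = "repressed", chosen = r)
  } else {
    ma <- mean(abs(a$contribution))
    mr <- mean(abs(r$contribution))
    if (ma > mr) list(direction = "activated", chosen = a)
    else if (mr > ma) list(direction = "repressed", chosen = r)
    else list(direction = "ambiguous", chosen = a)
  }
}

#' Score a single regulon
#'
#' Directional statistics: signed average fold change of the chosen group
#' (positive = regulator activated, negative = repressed), MAD of the chosen
#' group's log2 fold changes, and the logical-regulation fraction
#' `n_chosen / n_nonzero` (the share of informative regulon genes whose
#' fold-change direction is consistent with the chosen regulator activity;
#' always >= 0.5). Raw statistics ignore directionality: mean and MAD of the
#' log2 fold changes of all measured regulon genes.
#'
#' @param regulator regulator name (for the result row).
#' @param links this regulator's link rows (columns `gene`, `mode`).
#' @param de DE table.
#' @param minSize minimum number of measured genes (default 2; MAD and
#'   fractions degenerate at n = 1).
#' @return one-row data.frame with columns `regulator`, `direction`,
#'   `score`, `mad`, `n_total`, `n_chosen`, `logical_fraction`,
#'   `raw_score`, `raw_mad`, plus attribute `chosen` (the chosen group) for
#'   downstream enrichment testing, or `NULL` with attribute `skip_reason`
#'   when the regulon is unmeasured, below `minSize`, or uninformative.
#' @export
scoreRegulon <- function(regulator, links, de, minSize = 2L) {
  split <- splitRegulon(links, de)
  skip <- function(reason) {
    structure(list(NULL), class = "regdir_skip", regulator = regulator,
              reason = reason, n_measured = split$n_measured)
  }
  if (split$n_measured == 0L) return(skip("unmeasured"))
  if (split$n_measured < minSize) return(skip("below_min_size"))
  if (nrow(split$active) == 0L && nrow(split$repressed) == 0L)
    return(skip("uninformative"))
  ch <- chooseGroup(split)
  nNonzero <- nrow(split$active) + nrow(split$repressed)
  allFC <- c(split$active$log2fc, split$repressed$log2fc,
             rep(0, length(split$zero)))
  out <- data.frame(
    regulator = regulator,
    direction = ch$direction,
    # chosen-group contributions are all positive (activated) or all
    # negative (repressed), so their mean is already the signed score
    score = mean(ch$chosen$contribution),
    mad = madFC(ch$chosen$log2fc),
    n_total = split$n_measured,
    n_chosen = nrow(ch$chosen),
    logical_fraction = nrow(ch$chosen) / nNonzero,
    raw_score = mean(allFC),
    raw_mad = madFC(allFC),
    stringsAsFactors = FALSE
  )
  attr(out, "chosen") <- ch$chosen
  attr(out, "unmatched") <- split$unmatched
  out
}

#' Score all regulons with enrichment statistics
#'
#' Runs the direction-aware scoring for every regulator in a
#' [RegulonSet-class], attaches a gene-label permutation P-value per regulon
#' (see [permutationPValue()]), Benjamini-Hochberg adjusted P-values across
#' the batch, and the two classification schemes: P-value quantile classes
#' (1 = the 10% of regulons with the lowest adjusted P-values, see
#' [pvalueQuantileClass()]) and logical-fraction classes (1 = fraction in
#' \[0.90, 1\], see [fractionClass()]).
#'
#' The ranking statistic for the permutation test depends on `pvalueMode`:
#' `"directional"` ranks every gene by `d * s` where `s` is the signed
#' contribution for genes carrying a mode in the tested regulon and the
#' plain log2 fold change otherwise, and `d` is +1 for a
#' chosen-activated and -1 for a chosen-repressed regulon; the tested set
#' is the chosen group. `"raw"` ranks by log2 fold change and tests all
#' measured regulon genes.
#'
#' @param de DE table from [readDETable()].
#' @param regulons a [RegulonSet-class].
#' @param minSize minimum measured regulon size (default 2).
#' @param nPerm permutations per regulon (default 10000).
#' @param seed base RNG seed; regulon `i` (in alphabetical regulator order)
#'   uses `seed + i`, so results do not depend on input row order.
#' @param weightExponent GSEA weighting exponent (default 1).
#' @param exhaustive if `TRUE`, enumerate all gene sets instead of sampling
#'   when `choose(N, k) <= exhaustiveThreshold`.
#' @param exhaustiveThreshold cap for exhaustive enumeration (default 1e5).
#' @param pvalueMode `"directional"` or `"raw"` (see above).
#' @return a [RegulonActivity-class].
#' @export
scoreRegulons <- function(de, regulons, minSize = 2L, nPerm = 10000L,
                          seed = 1L, weightExponent = 1,
                          exhaustive = FALSE, exhaustiveThreshold = 1e5,
                          pvalueMode = c("directional", "raw")) {
  pvalueMode <- match.arg(pvalueMode)
  links <- regulonLinks(regulons)
  regs <- sort(unique(links$regulator))
  rows <- vector("list", length(regs))
  skipped <- list()
  unmatched <- character()

  for (i in seq_along(regs)) {
    reg <- regs[[i]]
    rl <- links[links$regulator == reg, , drop = FALSE]
    sc <- scoreRegulon(reg, rl, de, minSize = minSize)
    if (inherits(sc, "regdir_skip")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        regulator = attr(sc, "regulator"), reason = attr(sc, "reason"),
        n_measured = attr(sc, "n_measured"), stringsAsFactors = FALSE)
      next
    }
    unmatched <- c(unmatched, attr(sc, "unmatched"))
    chosen <- attr(sc, "chosen")
    if (pvalueMode == "directional") {
      d <- if (sc$direction == "repressed") -1 else 1
      stat <- de$log2fc
      midx <- .matchGenes(rl$gene, de)
      keep <- !is.na(midx)
      stat[midx[keep]] <- signedContribution(de$log2fc[midx[keep]],
                                             rl$mode[keep])
      stat <- d * stat
      setGenes <- chosen$gene
    } else {
      # raw mode: plain log2FC ranking, all measured regulon genes tested
      stat <- de$log2fc
      midx <- .matchGenes(rl$gene, de)
      setGenes <- de$gene[midx[!is.na(midx)]]
    }
    ranked <- rankedList(de$gene, stat)
    pv <- permutationPValue(ranked, setGenes, nPerm = nPerm,
                            seed = seed + i, weightExponent = weightExponent,
                            exhaustive = exhaustive,
                            exhaustiveThreshold = exhaustiveThreshold)
    sc$pvalue <- pv
    rows[[i]] <- sc
  }

  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(regulator = character(), direction = character(),
                      score = numeric(), mad = numeric(),
                      n_total = integer(), n_chosen = integer(),
                      logical_fraction = numeric(), raw_score = numeric(),
                      raw_mad = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  res$padj <- bhAdjust(res$pvalue)
  res$pclass <- pvalueQuantileClass(res$padj, res$regulator)
  res$fclass <- fractionClass(res$logical_fraction)
  res <- res[c("regulator", "direction", "score", "mad", "n_total",
               "n_chosen", "logical_fraction", "pvalue", "padj",
               "raw_score", "raw_mad", "pclass", "fclass")]
  rownames(res) <- NULL
  skippedDf <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(regulator = character(), reason = character(),
               n_measured = integer(), stringsAsFactors = FALSE)
  out <- new("RegulonActivity", results = res, skipped = skippedDf,
             params = list(minSize = minSize, nPerm = nPerm, seed = seed,
                           weightExponent = weightExponent,
                           exhaustive = exhaustive,
                           pvalueMode = pvalueMode))
  attr(out, "unmatched_genes") <- sort(unique(unmatched))
  out
}
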