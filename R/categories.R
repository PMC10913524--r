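#' Assign genes to categories at one hierarchy level
#'
#' Truncates each gene's category path at `level` (level 1 = main category)
#' and groups genes by the truncated path. Genes whose path is shallower
#' than `level` are kept at their full depth when `includeShallow = TRUE`
#' (the default) and excluded otherwise. With `includeShallow = TRUE` every
#' gene counted at level L falls under exactly one ancestor category at
#' level L - 1.
#'
#' @param categories a [CategorySet-class].
#' @param level hierarchy level (>= 1).
#' @param includeShallow keep genes with paths shallower than `level`.
#' @param sep separator used to label the truncated paths (default ".").
#' @return named list of character vectors (category label -> gene names).
#' @export
selectLevel <- function(categories, level, includeShallow = TRUE,
                        sep = ".") {
  stopifnot(level >= 1L)
  links <- categoryLinks(categories)
  if (nrow(links) == 0L) return(list())
  depth <- vapply(links$levels, length, 1L)
  keep <- depth >= level | includeShallow
  labels <- vapply(links$levels[keep], function(l)
    paste(l[seq_len(min(level, length(l)))], collapse = sep), "")
  sets <- split(links$gene[keep], labels)
  lapply(sets[order(names(sets))], unique)
}

#' Score one functional category
#'
#' Directionality-free gene-set statistics: mean and MAD of the member
#' genes' log2 fold changes, and the fractions of members that are up-,
#' down- and un-regulated (strict sign of log2FC; exactly-zero fold
#' changes form their own bin, so the three fractions always sum to 1).
#'
#' @param category category label (for the result row).
#' @param genes character vector of member gene names.
#' @param de DE table.
#' @param level hierarchy level the label was produced at (recorded in the
#'   output).
#' @param minSize minimum measured genes (default 2).
#' @return one-row data.frame (`category`, `level`, `avg_fc`, `mad`, `n`,
#'   `frac_up`, `frac_down`, `frac_zero`) or `NULL` when fewer than
#'   `minSize` members are measured.
#' @export
scoreCategory <- function(category, genes, de, level = NA_integer_,
                          minSize = 2L) {
  idx <- .matchGenes(genes, de)
  fc <- de$log2fc[idx[!is.na(idx)]]
  n <- length(fc)
  if (n < minSize) return(NULL)
  data.frame(category = category, level = level,
             avg_fc = mean(fc), mad = madFC(fc), n = n,
             frac_up = sum(fc > 0) / n, frac_down = sum(fc < 0) / n,
             frac_zero = sum(fc == 0) / n, stringsAsFactors = FALSE)
}

#' Score all categories at a hierarchy level
#'
#' Applies [scoreCategory()] to every category produced by [selectLevel()],
#' attaches permutation P-values (plain log2FC ranking, the category's
#' measured genes as the set) and BH adjustment across the batch. Genes
#' appearing under several sibling categories count in each; categories
#' below `minSize` are skipped and listed in `attr(x, "skipped")`.
#'
#' @inheritParams selectLevel
#' @inheritParams scoreRegulons
#' @return data.frame with the [scoreCategory()] columns plus `pvalue` and
#'   `padj`, sorted by category label.
#' @export
scoreCategories <- function(de, categories, level = 1L,
                            includeShallow = TRUE, minSize = 2L,
                            nPerm = 10000L, seed = 1L, weightExponent = 1,
                            exhaustive = FALSE, exhaustiveThreshold = 1e5) {
  sets <- selectLevel(categories, level, includeShallow = includeShallow)
  ranked <- rankedList(de$gene, de$log2fc)
  rows <- list()
  skipped <- character()
  nm <- names(sets)
  for (i in seq_along(sets)) {
    sc <- scoreCategory(nm[[i]], sets[[i]], de, level = level,
                        minSize = minSize)
    if (is.null(sc)) {
      skipped <- c(skipped, nm[[i]])
      next
    }
    idx <- .matchGenes(sets[[i]], de)
    sc$pvalue <- permutationPValue(ranked, de$gene[idx[!is.na(idx)]],
                                   nPerm = nPerm, seed = seed + i,
                                   weightExponent = weightExponent,
                                   exhaustive = exhaustive,
                                   exhaustiveThreshold = exhaustiveThreshold)
    rows[[length(rows) + 1L]] <- sc
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), level = integer(),
               avg_fc = numeric(), mad = numeric(), n = integer(),
               frac_up = numeric(), frac_down = numeric(),
               frac_zero = numeric(), pvalue = numeric(),
               stringsAsFactors = FALSE)
  res$padj <- bhAdjust(res$pvalue)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
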