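#' Per-gene regulon report
#'
#' Links every measured gene to all regulons it belongs to, carrying each
#' regulon's signed activity score and logical-regulation fraction so a
#' reader can judge which regulator most plausibly explains the gene's
#' expression change. Entries are sorted by descending logical fraction,
#' then descending absolute score, so the most plausible regulator comes
#' first; regulons that were skipped during scoring (below the minimum
#' size, unmeasured, uninformative) appear as entries with `NA` score and
#' fraction.
#'
#' @param de DE table from [readDETable()].
#' @param activity a [RegulonActivity-class] from [scoreRegulons()].
#' @param regulons the [RegulonSet-class] the activities were computed from.
#' @return data.frame with one row per measured gene: `gene`, `log2fc`,
#'   `pvalue`, `n_regulons`, and list column `entries` (each element a
#'   data.frame with `regulator`, `score`, `logical_fraction`).
#' @export
buildGeneReport <- function(de, activity, regulons) {
  links <- regulonLinks(regulons)
  res <- activities(activity)
  idx <- .matchGenes(links$gene, de)
  linkGene <- de$gene[idx]                # DE-side gene name, NA if unmatched
  byGene <- split(links$regulator[!is.na(idx)], linkGene[!is.na(idx)])

  entriesFor <- function(gene) {
    regs <- sort(unique(byGene[[gene]]))
    if (is.null(regs) || length(regs) == 0L)
      return(data.frame(regulator = character(), score = numeric(),
                        logical_fraction = numeric(),
                        stringsAsFactors = FALSE))
    m <- match(regs, res$regulator)
    e <- data.frame(regulator = regs,
                    score = res$score[m],
                    logical_fraction = res$logical_fraction[m],
                    stringsAsFactors = FALSE)
    # scored entries first, most plausible regulator on top; NA (skipped
    # regulons) last
    ord <- order(is.na(e$logical_fraction), -e$logical_fraction,
                 -abs(e$score), e$regulator, na.last = FALSE)
    e[ord, , drop = FALSE]
  }

  report <- data.frame(gene = de$gene, log2fc = de$log2fc,
                       pvalue = de$pvalue, stringsAsFactors = FALSE)
  report$entries <- lapply(de$gene, entriesFor)
  report$n_regulons <- vapply(report$entries, nrow, 1L)
  report[c("gene", "log2fc", "pvalue", "n_regulons", "entries")]
}

#' Write the per-gene regulon report
#'
#' Wide TSV with one row per gene and repeated column triplets
#' `regulon_i`, `fc_i`, `fraction_i` (the regulon's signed average fold
#' change and logical-regulation fraction, `NA` for skipped regulons), up
#' to the maximum number of regulon memberships in the table.
#'
#' @param report gene report from [buildGeneReport()].
#' @param path output TSV path.
#' @return the flattened data.frame, invisibly written to `path`.
#' @export
writeGeneReport <- function(report, path) {
  kmax <- max(c(0L, report$n_regulons))
  flat <- report[c("gene", "log2fc", "pvalue", "n_regulons")]
  for (j in seq_len(kmax)) {
    flat[[paste0("regulon_", j)]] <- vapply(report$entries, function(e)
      if (nrow(e) >= j) e$regulator[[j]] else NA_character_, "")
    flat[[paste0("fc_", j)]] <- vapply(report$entries, function(e)
      if (nrow(e) >= j) e$score[[j]] else NA_real_, numeric(1))
    flat[[paste0("fraction_", j)]] <- vapply(report$entries, function(e)
      if (nrow(e) >= j) e$logical_fraction[[j]] else NA_real_, numeric(1))
  }
  writeReportTable(flat, path)
  invisible(flat)
}
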