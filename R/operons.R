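#' Tabulate fold changes within operons
#'
#' Builds one report row per operon: member genes in transcription order
#' with their log2 fold changes and adjusted P-values (genes absent from
#' the DE table are retained with `NA` markers), and the number of operons
#' each gene belongs to, counted across the whole operon table. Use
#' [flagAnomalies()] to screen the report for discordant operons.
#'
#' @param operons an [OperonSet-class].
#' @param de DE table from [readDETable()].
#' @return data.frame with columns `operon_id`, `n_genes`, `n_measured`
#'   and list columns `genes`, `log2fcs`, `padjs`, `n_operons_per_gene`,
#'   plus logical `discordant` (initialized `FALSE`) and list column
#'   `discordant_pairs`.
#' @export
buildOperonReport <- function(operons, de) {
  defs <- operonDefs(operons)
  allGenes <- unlist(defs$genes, use.names = FALSE)
  counts <- table(.normalizeKey(allGenes))
  n <- nrow(defs)
  report <- data.frame(operon_id = defs$operon_id,
                       n_genes = vapply(defs$genes, length, 1L),
                       stringsAsFactors = FALSE)
  report$genes <- defs$genes
  report$log2fcs <- lapply(defs$genes, function(g) {
    idx <- .matchGenes(g, de)
    de$log2fc[idx]          # NA where unmeasured
  })
  report$padjs <- lapply(defs$genes, function(g) {
    idx <- .matchGenes(g, de)
    de$padj[idx]
  })
  report$n_measured <- vapply(report$log2fcs,
                              function(x) sum(!is.na(x)), 1L)
  report$n_operons_per_gene <- lapply(defs$genes, function(g)
    as.integer(counts[.normalizeKey(g)]))
  report$discordant <- FALSE
  report$discordant_pairs <- replicate(n, character(0), simplify = FALSE)
  report
}

#' Flag operons with discordant internal regulation
#'
#' An operon is discordant when it contains a pair of genes with
#' opposite-sign log2 fold changes that are both substantial
#' (`|log2FC| >= fcThreshold`) and both significant
#' (`padj <= padjThreshold`) — the signature of an internal promoter or a
#' mis-annotated operon, since co-transcribed genes should move together.
#' Flagging is symmetric in gene order and invariant under a global sign
#' flip of the fold changes, and raising `fcThreshold` can only reduce the
#' number of flagged operons.
#'
#' @param report operon report from [buildOperonReport()].
#' @param fcThreshold minimum absolute log2 fold change for both genes of
#'   a pair (default 1.0).
#' @param padjThreshold maximum adjusted P-value for both genes
#'   (default 0.05).
#' @return the report with `discordant` and `discordant_pairs` filled in.
#' @export
flagAnomalies <- function(report, fcThreshold = 1.0, padjThreshold = 0.05) {
  stopifnot(fcThreshold > 0, padjThreshold > 0)
  for (i in seq_len(nrow(report))) {
    fc <- report$log2fcs[[i]]
    padj <- report$padjs[[i]]
    genes <- report$genes[[i]]
    sig <- !is.na(fc) & abs(fc) >= fcThreshold &
      !is.na(padj) & padj <= padjThreshold
    up <- which(sig & fc > 0)
    down <- which(sig & fc < 0)
    pairs <- character(0)
    if (length(up) && length(down)) {
      grid <- expand.grid(a = up, b = down)
      pairs <- paste(genes[pmin(grid$a, grid$b)],
                     genes[pmax(grid$a, grid$b)], sep = "|")
    }
    report$discordant_pairs[[i]] <- pairs
    report$discordant[[i]] <- length(pairs) > 0L
  }
  report
}

#' Write the per-gene operon report table
#'
#' Long-format TSV mirroring a spreadsheet operon view: one row per operon
#' member gene with its fold change, adjusted P-value, the number of
#' operons the gene belongs to, the operon gene context, and the operon's
#' discordance flag.
#'
#' @param report (flagged) operon report.
#' @param path output TSV path.
#' @return the expanded data.frame, invisibly written to `path`.
#' @export
writeOperonReport <- function(report, path) {
  rows <- lapply(seq_len(nrow(report)), function(i) {
    genes <- report$genes[[i]]
    data.frame(operon_id = report$operon_id[[i]],
               gene = genes,
               log2fc = report$log2fcs[[i]],
               padj = report$padjs[[i]],
               n_operons = report$n_operons_per_gene[[i]],
               operon_context = paste(genes, collapse = "-"),
               discordant = report$discordant[[i]],
               discordant_pairs = paste(report$discordant_pairs[[i]],
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  })
  flat <- do.call(rbind, rows)
  writeReportTable(flat, path)
  invisible(flat)
}
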