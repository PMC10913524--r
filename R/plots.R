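#' @importFrom ggplot2 ggplot aes geom_point scale_size_area labs
#'   scale_y_log10 theme_bw geom_vline geom_hline scale_colour_manual
#'   ggsave .data
NULL

# default colours for the five reliability / P-value classes
.classColours <- c("1" = "#1f78b4", "2" = "#e6c300", "3" = "#808080",
                   "4" = "#ff7f00", "5" = "#b2df8a")

.savePlot <- function(plot, path, format = c("svg", "png"),
                      width = 7, height = 5) {
  format <- match.arg(format)
  if (!grepl(paste0("\\.", format, "$"), path))
    path <- paste0(path, ".", format)
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  device = format, dpi = 150)
  path
}

.companionPath <- function(path) paste0(sub("\\.[a-zA-Z]+$", "", path),
                                        ".tsv")

#' Regulon bubble plot
#'
#' Signed average fold change against the MAD of the fold change, one
#' bubble per regulon; bubble size is the number of genes (all measured
#' genes in raw mode, the chosen group in directional mode) and colour
#' intensity encodes the P-value quantile class (class 1 = the 10% of
#' regulons with the lowest adjusted P-values, darkest). A companion TSV
#' with exactly the plotted rows is always written next to the image, so
#' the plot is a pure function of that table.
#'
#' @param activity a [RegulonActivity-class].
#' @param path output image path (extension added from `format`).
#' @param mode `"directional"` (default) plots `score`/`mad`/`n_chosen`;
#'   `"raw"` plots `raw_score`/`raw_mad`/`n_total`.
#' @param maxPclass keep only regulons with P-value quantile class <=
#'   this (e.g. 2 keeps the 20% lowest adjusted P-values); `NULL` keeps
#'   all.
#' @param labels character vector of regulator names to label, or `TRUE`
#'   for all.
#' @param format `"svg"` (default) or `"png"`.
#' @return invisible list with `plot`, `data` (the companion table),
#'   `image` and `table` paths.
#' @export
bubblePlot <- function(activity, path, mode = c("directional", "raw"),
                       maxPclass = NULL, labels = FALSE,
                       format = c("svg", "png")) {
  mode <- match.arg(mode)
  res <- activities(activity)
  if (!is.null(maxPclass)) {
    res <- res[res$pclass <= maxPclass, , drop = FALSE]
    if (nrow(res) == 0L)
      stop("no regulons left after filter maxPclass <= ", maxPclass,
           call. = FALSE)
  }
  if (nrow(res) == 0L) stop("no regulons to plot", call. = FALSE)
  df <- data.frame(regulator = res$regulator,
                   x = if (mode == "raw") res$raw_score else res$score,
                   y = if (mode == "raw") res$raw_mad else res$mad,
                   n = if (mode == "raw") res$n_total else res$n_chosen,
                   pclass = res$pclass, stringsAsFactors = FALSE)
  df <- df[order(df$regulator), , drop = FALSE]
  p <- ggplot(df, aes(x = .data$x, y = .data$y, size = .data$n,
                      colour = factor(.data$pclass))) +
    geom_point(alpha = 0.8) +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    scale_size_area(max_size = 12, name = "genes") +
    scale_colour_manual(values = .classColours, name = "P class",
                        drop = FALSE) +
    labs(x = if (mode == "raw") "average FC (log2)" else
           "signed average FC (log2)",
         y = "mad FC") +
    theme_bw()
  if (isTRUE(labels) || is.character(labels)) {
    lab <- if (isTRUE(labels)) df else
      df[df$regulator %in% labels, , drop = FALSE]
    p <- p + ggplot2::geom_text(data = lab,
      aes(label = .data$regulator), size = 3, vjust = -1,
      show.legend = FALSE)
  }
  img <- .savePlot(p, path, format)
  tsv <- .companionPath(img)
  writeReportTable(df, tsv)
  invisible(list(plot = p, data = df, image = img, table = tsv))
}

#' Regulon volcano plot
#'
#' Adjusted P-values (log-scaled axis) against the signed average fold
#' change, coloured by the logical-fraction reliability class. By default
#' only regulons whose logical fraction reaches 0.67 (classes 1-4) are
#' drawn: fractions below that mean a third or more of the informative
#' genes contradict the called direction. A companion TSV of the plotted
#' rows is always written.
#'
#' @param activity a [RegulonActivity-class].
#' @param path output image path.
#' @param minFclass keep classes <= this (default 4, dropping class 5 and
#'   unclassified); use 5 to keep everything.
#' @param format `"svg"` or `"png"`.
#' @return invisible list with `plot`, `data`, `image`, `table`.
#' @export
volcanoPlot <- function(activity, path, minFclass = 4L,
                        format = c("svg", "png")) {
  res <- activities(activity)
  keep <- !is.na(res$fclass) & res$fclass <= minFclass
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L)
    stop("no regulons left after filter fclass <= ", minFclass,
         call. = FALSE)
  df <- data.frame(regulator = res$regulator, x = res$score,
                   y = pmax(res$padj, .Machine$double.xmin),
                   fclass = res$fclass, stringsAsFactors = FALSE)
  df <- df[order(df$regulator), , drop = FALSE]
  p <- ggplot(df, aes(x = .data$x, y = .data$y,
                      colour = factor(.data$fclass))) +
    geom_point(size = 2.5, alpha = 0.85) +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    scale_y_log10() +
    scale_colour_manual(values = .classColours, name = "fraction class",
                        drop = FALSE) +
    labs(x = "signed average FC (log2)", y = "adjusted P-value") +
    theme_bw()
  img <- .savePlot(p, path, format)
  tsv <- .companionPath(img)
  writeReportTable(df, tsv)
  invisible(list(plot = p, data = df, image = img, table = tsv))
}

#' Spread plot of gene-level fold changes per set
#'
#' One row per gene set (regulon or category), one tick per member gene at
#' its log2 fold change, rows ordered by the set's plain average fold
#' change. Regulation directionality is deliberately not applied here —
#' the plot shows the raw expression spread. With `topN`, only the
#' `topN/2` sets with the highest and the `topN/2` with the lowest
#' average fold change are kept (set `side` to keep one end only). A
#' companion TSV of the plotted ticks is always written.
#'
#' @param de DE table.
#' @param sets named list of character vectors (set name -> member
#'   genes), e.g. regulon gene lists or [selectLevel()] output.
#' @param path output image path.
#' @param topN keep only the most strongly affected sets (`NULL` = all).
#' @param side `"both"` (default), `"up"` or `"down"`.
#' @param minSize minimum measured genes per set (default 1).
#' @param format `"svg"` or `"png"`.
#' @return invisible list with `plot`, `data` (columns `set`, `gene`,
#'   `log2fc`, `avg_fc`, `rank`), `image`, `table`.
#' @export
spreadPlot <- function(de, sets, path, topN = NULL, side = "both",
                       minSize = 1L, format = c("svg", "png")) {
  stopifnot(length(sets) > 0L, !is.null(names(sets)))
  rows <- lapply(names(sets), function(nm) {
    idx <- .matchGenes(sets[[nm]], de)
    idx <- idx[!is.na(idx)]
    if (length(idx) < minSize) return(NULL)
    data.frame(set = nm, gene = de$gene[idx], log2fc = de$log2fc[idx],
               avg_fc = mean(de$log2fc[idx]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L)
    stop("no measured sets to plot", call. = FALSE)
  setStats <- unique(df[c("set", "avg_fc")])
  setStats <- setStats[order(-setStats$avg_fc, setStats$set), ,
                       drop = FALSE]
  if (!is.null(topN) && topN < nrow(setStats)) {
    nUp <- switch(side, both = ceiling(topN / 2), up = topN, down = 0L)
    nDown <- switch(side, both = topN - ceiling(topN / 2), up = 0L,
                    down = topN)
    keep <- c(utils::head(setStats$set, nUp),
              utils::tail(setStats$set, nDown))
    setStats <- setStats[setStats$set %in% keep, , drop = FALSE]
    df <- df[df$set %in% keep, , drop = FALSE]
  }
  setStats$rank <- seq_len(nrow(setStats))
  df$rank <- setStats$rank[match(df$set, setStats$set)]
  df <- df[order(df$rank, df$gene), , drop = FALSE]
  p <- ggplot(df, aes(x = .data$log2fc,
                      y = stats::reorder(.data$set, -.data$rank))) +
    geom_point(shape = "|", size = 4, alpha = 0.8) +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    labs(x = "fold change (log2)", y = NULL) +
    theme_bw()
  img <- .savePlot(p, path, format)
  tsv <- .companionPath(img)
  writeReportTable(df, tsv)
  invisible(list(plot = p, data = df, image = img, table = tsv))
}

#' Gene sets of a RegulonSet for spread plotting
#'
#' @param regulons a [RegulonSet-class].
#' @return named list regulator -> character vector of annotated genes.
#' @export
regulonGeneSets <- function(regulons) {
  links <- regulonLinks(regulons)
  lapply(split(links$gene, links$regulator), unique)
}
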