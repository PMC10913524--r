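#' Read a differential-expression table
#'
#' Reads a per-gene DE results export (the shape of a DESeq2 results table):
#' gene name, optional unique identifier (e.g. a locus tag), log2 fold
#' change, P-value and adjusted P-value. Rows whose log2 fold change cannot
#' be parsed (e.g. "NA") are dropped and counted in the load report attached
#' as `attr(x, "load_report")`.
#'
#' @param path TSV or CSV file (delimiter sniffed from the extension).
#' @param columns named character vector mapping the canonical fields
#'   `gene`, `uid`, `log2fc`, `pvalue`, `padj` to column names in the file.
#'   `uid`, `pvalue` and `padj` entries may name columns absent from the
#'   file; `gene` and `log2fc` are mandatory.
#' @param delim override the sniffed delimiter.
#' @return data.frame with columns `gene`, `uid`, `log2fc`, `pvalue`,
#'   `padj` and attribute `load_report` (list with `total`, `parsed`,
#'   `dropped`).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tlog2FC\tpvalue", "iolA\t-2.03\t0.001"), tf)
#' de <- readDETable(tf)
#' attr(de, "load_report")$dropped
#' @export
readDETable <- function(path,
                        columns = c(gene = "gene", uid = "uid",
                                    log2fc = "log2FC", pvalue = "pvalue",
                                    padj = "padj"),
                        delim = NULL) {
  defaults <- c(gene = "gene", uid = "uid", log2fc = "log2FC",
                pvalue = "pvalue", padj = "padj")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- .readTable(path, delim)
  for (field in c("gene", "log2fc"))
    if (!columns[[field]] %in% names(raw))
      stop("DE table: missing mandatory column: ", columns[[field]],
           call. = FALSE)
  total <- nrow(raw)
  de <- data.frame(
    gene = trimws(as.character(raw[[columns[["gene"]]]])),
    uid = if (columns[["uid"]] %in% names(raw))
      trimws(as.character(raw[[columns[["uid"]]]])) else NA_character_,
    log2fc = suppressWarnings(as.numeric(raw[[columns[["log2fc"]]]])),
    pvalue = if (columns[["pvalue"]] %in% names(raw))
      suppressWarnings(as.numeric(raw[[columns[["pvalue"]]]])) else NA_real_,
    padj = if (columns[["padj"]] %in% names(raw))
      suppressWarnings(as.numeric(raw[[columns[["padj"]]]])) else NA_real_,
    stringsAsFactors = FALSE
  )
  keep <- is.finite(de$log2fc) & nzchar(de$gene)
  de <- de[keep, , drop = FALSE]
  rownames(de) <- NULL
  for (col in c("pvalue", "padj")) {
    bad <- !is.na(de[[col]]) & (de[[col]] < 0 | de[[col]] > 1)
    if (any(bad))
      stop("DE table: ", col, " outside [0,1] for gene(s): ",
           paste(utils::head(de$gene[bad], 5), collapse = ", "),
           call. = FALSE)
  }
  dupKey <- paste(.normalizeKey(de$gene), .normalizeKey(de$uid), sep = "\r")
  if (anyDuplicated(dupKey))
    stop("DE table: duplicated (gene, uid): ",
         paste(unique(de$gene[duplicated(dupKey)]), collapse = ", "),
         call. = FALSE)
  attr(de, "load_report") <- list(total = total, parsed = nrow(de),
                                  dropped = total - nrow(de))
  de
}

#' Read a regulon annotation table
#'
#' One row per regulator-gene link with a regulation qualifier (the shape of
#' a Subtiwiki-style regulon export). Every qualifier must be covered by the
#' supplied [QualifierMap-class]; unmapped qualifiers are a hard error that
#' lists them all, so no link ever enters the analysis without a defined
#' regulation mode. Duplicate regulator-gene links with conflicting modes
#' keep the first occurrence with a warning.
#'
#' @param path TSV or CSV file.
#' @param qmap a [QualifierMap-class]; defaults to [defaultQualifierMap()].
#' @param columns named character vector mapping `regulator`, `gene`,
#'   `qualifier` to file column names.
#' @param delim override the sniffed delimiter.
#' @return a [RegulonSet-class].
#' @export
readRegulonTable <- function(path, qmap = defaultQualifierMap(),
                             columns = c(regulator = "regulator",
                                         gene = "gene",
                                         qualifier = "qualifier"),
                             delim = NULL) {
  defaults <- c(regulator = "regulator", gene = "gene",
                qualifier = "qualifier")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- .readTable(path, delim)
  .requireColumns(raw, unname(columns), "regulon table")
  links <- data.frame(
    regulator = trimws(as.character(raw[[columns[["regulator"]]]])),
    gene = trimws(as.character(raw[[columns[["gene"]]]])),
    qualifier = trimws(as.character(raw[[columns[["qualifier"]]]])),
    stringsAsFactors = FALSE
  )
  RegulonSet(links, qmap)
}

#' Build a RegulonSet from a link table
#'
#' @param links data.frame with columns `regulator`, `gene`, `qualifier`.
#' @param qmap a [QualifierMap-class].
#' @return a [RegulonSet-class].
#' @export
RegulonSet <- function(links, qmap = defaultQualifierMap()) {
  .requireColumns(links, c("regulator", "gene", "qualifier"), "regulon links")
  key <- .normalizeKey(links$qualifier)
  mode <- unname(qmap@map[key])
  if (anyNA(mode)) {
    unmapped <- sort(unique(links$qualifier[is.na(mode)]))
    stop("unmapped regulation qualifier(s): ",
         paste(unmapped, collapse = ", "),
         "; extend the qualifier map to cover them", call. = FALSE)
  }
  links$mode <- mode
  pairKey <- paste(.normalizeKey(links$regulator),
                   .normalizeKey(links$gene), sep = "\r")
  dup <- duplicated(pairKey)
  if (any(dup)) {
    firstMode <- links$mode[match(pairKey, pairKey)]
    if (any(links$mode[dup] != firstMode[dup]))
      warning("conflicting regulation modes for ",
              sum(links$mode[dup] != firstMode[dup]),
              " duplicated regulator-gene link(s); keeping the first",
              call. = FALSE)
    links <- links[!dup, , drop = FALSE]
  }
  rownames(links) <- NULL
  new("RegulonSet", links = links[c("regulator", "gene", "qualifier", "mode")])
}

#' Read a functional-category table
#'
#' Gene-to-category links where each category is a hierarchical path such as
#' `"Metabolism.Carbon metabolism.Glycolysis"` (level 1 = main category).
#' Rows with an empty path are excluded and counted in the load report.
#'
#' @param path TSV or CSV file.
#' @param columns named character vector mapping `gene` and `category` to
#'   file column names.
#' @param sep path-level separator inside the category column (default ".").
#' @param delim override the sniffed delimiter.
#' @return a [CategorySet-class] with attribute `load_report`.
#' @export
readCategoryTable <- function(path,
                              columns = c(gene = "gene",
                                          category = "category"),
                              sep = ".", delim = NULL) {
  defaults <- c(gene = "gene", category = "category")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- .readTable(path, delim)
  .requireColumns(raw, unname(columns), "category table")
  gene <- trimws(as.character(raw[[columns[["gene"]]]]))
  path_ <- trimws(as.character(raw[[columns[["category"]]]]))
  total <- length(gene)
  levels <- strsplit(path_, sep, fixed = TRUE)
  levels <- lapply(levels, function(l) trimws(l[nzchar(trimws(l))]))
  ok <- nzchar(gene) & !is.na(path_) & vapply(levels, length, 1L) > 0L
  links <- data.frame(gene = gene[ok], path = path_[ok],
                      stringsAsFactors = FALSE)
  links$levels <- levels[ok]
  rownames(links) <- NULL
  obj <- new("CategorySet", links = links)
  attr(obj, "load_report") <- list(total = total, parsed = sum(ok),
                                   dropped = total - sum(ok))
  obj
}

#' Read an operon table
#'
#' Two layouts are accepted: one row per operon with a delimited member-gene
#' list (columns `operon` and `genes`), or one row per gene with its
#' position (columns `operon`, `gene`, `position`). Gene order is preserved
#' (transcription order); operons with zero parsable genes are excluded and
#' counted in the load report.
#'
#' @param path TSV or CSV file.
#' @param geneSep separator inside the gene-list column (default ";").
#' @param columns named character vector mapping `operon`, `genes`, `gene`,
#'   `position` to file column names (only the layout in use is needed).
#' @param delim override the sniffed delimiter.
#' @return an [OperonSet-class] with attribute `load_report`.
#' @export
readOperonTable <- function(path, geneSep = ";",
                            columns = c(operon = "operon", genes = "genes",
                                        gene = "gene",
                                        position = "position"),
                            delim = NULL) {
  defaults <- c(operon = "operon", genes = "genes", gene = "gene",
                position = "position")
  defaults[names(columns)] <- columns
  columns <- defaults
  raw <- .readTable(path, delim)
  if (!columns[["operon"]] %in% names(raw))
    stop("operon table: missing mandatory column: ", columns[["operon"]],
         call. = FALSE)
  if (columns[["genes"]] %in% names(raw)) {
    ids <- trimws(as.character(raw[[columns[["operon"]]]]))
    geneLists <- strsplit(as.character(raw[[columns[["genes"]]]]),
                          geneSep, fixed = TRUE)
    geneLists <- lapply(geneLists, function(g) trimws(g[nzchar(trimws(g))]))
  } else if (all(c(columns[["gene"]], columns[["position"]]) %in% names(raw))) {
    ids0 <- trimws(as.character(raw[[columns[["operon"]]]]))
    gene <- trimws(as.character(raw[[columns[["gene"]]]]))
    pos <- suppressWarnings(as.numeric(raw[[columns[["position"]]]]))
    ord <- order(match(ids0, unique(ids0)), pos)
    ids <- unique(ids0)
    geneLists <- lapply(ids, function(i) {
      g <- gene[ord][ids0[ord] == i]
      g[nzchar(g)]
    })
  } else {
    stop("operon table: need either a '", columns[["genes"]],
         "' column or '", columns[["gene"]], "' + '", columns[["position"]],
         "' columns", call. = FALSE)
  }
  total <- length(ids)
  ok <- vapply(geneLists, length, 1L) > 0L & nzchar(ids)
  operons <- data.frame(operon_id = ids[ok], stringsAsFactors = FALSE)
  operons$genes <- geneLists[ok]
  rownames(operons) <- NULL
  obj <- new("OperonSet", operons = operons)
  attr(obj, "load_report") <- list(total = total, parsed = sum(ok),
                                   dropped = total - sum(ok))
  obj
}

#' Write / read report tables
#'
#' All report tables are UTF-8 TSV with a header, "." as the decimal
#' separator, and full double precision, so a written table re-read with
#' [readReportTable()] reproduces the values (strings and integers
#' bit-exactly, reals to well within 1e-12). List columns are collapsed
#' with ";".
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @return `writeReportTable()` returns `path` invisibly;
#'   `readReportTable()` returns a data.frame.
#' @export
writeReportTable <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.list(out[[col]]))
      out[[col]] <- vapply(out[[col]], paste, "", collapse = ";")
    if (is.double(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), "")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeReportTable
#' @export
readReportTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", fileEncoding = "UTF-8")
}

#' Load report of a reader
#'
#' Readers attach a load report accounting for every input row
#' (`parsed + dropped = total`).
#'
#' @param x object returned by a reader.
#' @return list with `total`, `parsed`, `dropped`.
#' @export
loadReport <- function(x) attr(x, "load_report")
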