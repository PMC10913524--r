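#' Read a key=value run configuration file
#'
#' One `key = value` pair per line, `#` comments and blank lines ignored.
#' Values are kept as strings; numeric coercion happens where the
#' consuming function expects a number.
#'
#' @param path config file path.
#' @return named list of strings.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
  bad <- !grepl("=", body, fixed = TRUE)
  if (any(bad))
    stop("config line without '=': ", body[bad][1], call. = FALSE)
  kv <- strsplit(body, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals
}

.writeRunConfig <- function(config, path) {
  writeLines(paste0(names(config), " = ",
                    vapply(config, function(v) paste(v, collapse = ","),
                           "")),
             path)
  invisible(path)
}

.runLog <- function(outDir, lines) {
  writeLines(lines, file.path(outDir, "run_log.txt"))
  invisible(NULL)
}

#' End-to-end regulon analysis run
#'
#' Reads the DE table and regulon annotation, scores all regulons
#' direction-aware (see [scoreRegulons()]), and writes to `outDir`:
#' `regulon_activity.tsv` (the full per-regulon report),
#' `regulon_skipped.tsv`, `run_config.txt` (the fully serialized
#' parameters, for provenance) and `run_log.txt` (row counts, skipped
#' regulons, unmatched annotation genes). Two runs with identical inputs,
#' parameters and seed produce byte-identical outputs.
#'
#' @param deFile DE table path.
#' @param regulonFile regulon annotation path.
#' @param outDir output directory (created if needed).
#' @param qualifierMapFile optional qualifier map file; default map
#'   otherwise.
#' @param deColumns,regulonColumns column mappings for the readers.
#' @inheritParams scoreRegulons
#' @return the [RegulonActivity-class], invisibly.
#' @export
runRegulons <- function(deFile, regulonFile, outDir,
                        qualifierMapFile = NULL,
                        deColumns = c(gene = "gene", uid = "uid",
                                      log2fc = "log2FC",
                                      pvalue = "pvalue", padj = "padj"),
                        regulonColumns = c(regulator = "regulator",
                                           gene = "gene",
                                           qualifier = "qualifier"),
                        minSize = 2L, nPerm = 10000L, seed = 1L,
                        weightExponent = 1, exhaustive = FALSE,
                        pvalueMode = "directional") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  qmap <- if (is.null(qualifierMapFile)) defaultQualifierMap() else
    readQualifierMap(qualifierMapFile)
  de <- readDETable(deFile, columns = deColumns)
  regulons <- readRegulonTable(regulonFile, qmap = qmap,
                               columns = regulonColumns)
  act <- scoreRegulons(de, regulons, minSize = minSize, nPerm = nPerm,
                       seed = seed, weightExponent = weightExponent,
                       exhaustive = exhaustive, pvalueMode = pvalueMode)
  writeReportTable(activities(act),
                   file.path(outDir, "regulon_activity.tsv"))
  writeReportTable(skippedRegulons(act),
                   file.path(outDir, "regulon_skipped.tsv"))
  .writeRunConfig(c(list(de = deFile, regulons = regulonFile,
                         qualifier_map = qualifierMapFile %||% "default"),
                    runParams(act)),
                  file.path(outDir, "run_config.txt"))
  lr <- loadReport(de)
  .runLog(outDir, c(
    sprintf("de_rows_total=%d", lr$total),
    sprintf("de_rows_parsed=%d", lr$parsed),
    sprintf("de_rows_dropped=%d", lr$dropped),
    sprintf("regulons_scored=%d", nrow(activities(act))),
    sprintf("regulons_skipped=%d", nrow(skippedRegulons(act))),
    sprintf("unmatched_annotation_genes=%d",
            length(attr(act, "unmatched_genes")))))
  invisible(act)
}

#' End-to-end functional-category run
#'
#' Scores categories at one hierarchy level (see [scoreCategories()]) and
#' writes `category_activity.tsv`, `run_config.txt` and `run_log.txt` to
#' `outDir`.
#'
#' @param deFile DE table path.
#' @param categoryFile category table path.
#' @param outDir output directory.
#' @param categoryColumns column mapping for [readCategoryTable()].
#' @param pathSep category path separator.
#' @inheritParams scoreCategories
#' @return the category results data.frame, invisibly.
#' @export
runCategories <- function(deFile, categoryFile, outDir, level = 1L,
                          includeShallow = TRUE,
                          categoryColumns = c(gene = "gene",
                                              category = "category"),
                          pathSep = ".", minSize = 2L, nPerm = 10000L,
                          seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  de <- readDETable(deFile)
  categories <- readCategoryTable(categoryFile, columns = categoryColumns,
                                  sep = pathSep)
  res <- scoreCategories(de, categories, level = level,
                         includeShallow = includeShallow,
                         minSize = minSize, nPerm = nPerm, seed = seed)
  writeReportTable(res, file.path(outDir, "category_activity.tsv"))
  .writeRunConfig(list(de = deFile, categories = categoryFile,
                       level = level, include_shallow = includeShallow,
                       min_size = minSize, n_perm = nPerm, seed = seed),
                  file.path(outDir, "run_config.txt"))
  .runLog(outDir, c(
    sprintf("categories_scored=%d", nrow(res)),
    sprintf("categories_skipped=%d", length(attr(res, "skipped")))))
  invisible(res)
}

#' End-to-end per-gene regulon report run
#'
#' Scores regulons, then writes the per-gene report (`gene_report.tsv`)
#' linking every measured gene to its regulons with their signed scores
#' and logical fractions.
#'
#' @inheritParams runRegulons
#' @return the gene report data.frame, invisibly.
#' @export
runGenes <- function(deFile, regulonFile, outDir,
                     qualifierMapFile = NULL, minSize = 2L,
                     nPerm = 10000L, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  qmap <- if (is.null(qualifierMapFile)) defaultQualifierMap() else
    readQualifierMap(qualifierMapFile)
  de <- readDETable(deFile)
  regulons <- readRegulonTable(regulonFile, qmap = qmap)
  act <- scoreRegulons(de, regulons, minSize = minSize, nPerm = nPerm,
                       seed = seed)
  report <- buildGeneReport(de, act, regulons)
  writeGeneReport(report, file.path(outDir, "gene_report.tsv"))
  .writeRunConfig(list(de = deFile, regulons = regulonFile,
                       min_size = minSize, n_perm = nPerm, seed = seed),
                  file.path(outDir, "run_config.txt"))
  .runLog(outDir, sprintf("genes_reported=%d", nrow(report)))
  invisible(report)
}

#' End-to-end operon screen run
#'
#' Builds the operon report, flags discordant operons, and writes
#' `operon_report.tsv` (long format, one row per operon member gene).
#'
#' @param deFile DE table path.
#' @param operonFile operon table path.
#' @param outDir output directory.
#' @param fcThreshold,padjThreshold see [flagAnomalies()].
#' @param geneSep member-gene separator in the operon table.
#' @return the flagged operon report, invisibly.
#' @export
runOperons <- function(deFile, operonFile, outDir, fcThreshold = 1.0,
                       padjThreshold = 0.05, geneSep = ";") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  de <- readDETable(deFile)
  operons <- readOperonTable(operonFile, geneSep = geneSep)
  report <- flagAnomalies(buildOperonReport(operons, de),
                          fcThreshold = fcThreshold,
                          padjThreshold = padjThreshold)
  writeOperonReport(report, file.path(outDir, "operon_report.tsv"))
  .writeRunConfig(list(de = deFile, operons = operonFile,
                       fc_threshold = fcThreshold,
                       padj_threshold = padjThreshold),
                  file.path(outDir, "run_config.txt"))
  .runLog(outDir, c(
    sprintf("operons_reported=%d", nrow(report)),
    sprintf("operons_discordant=%d", sum(report$discordant))))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
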