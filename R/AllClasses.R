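#' @import methods
NULL

#' Qualifier-to-mode mapping
#'
#' Maps the free-text regulation qualifiers found in regulon annotation
#' exports (e.g. "activation", "sigma factor", "negative regulation") onto the
#' two regulation modes used throughout the package: `"up"` (the regulator
#' increases expression of the target) and `"down"` (the regulator represses
#' it). Matching is case-insensitive and whitespace-insensitive.
#'
#' @slot map named character vector; names are normalized qualifiers, values
#'   are `"up"` or `"down"`.
#' @seealso [defaultQualifierMap()], [readQualifierMap()]
#' @export
setClass("QualifierMap", representation(map = "character"))

setValidity("QualifierMap", function(object) {
  m <- object@map
  if (length(m) == 0L) return("qualifier map is empty")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    return("all qualifiers must be named")
  if (!all(m %in% c("up", "down")))
    return("modes must be 'up' or 'down'")
  if (anyDuplicated(names(m)))
    return("duplicated qualifier after normalization")
  TRUE
})

#' Regulon annotation
#'
#' One row per regulator-gene link, with the raw qualifier from the source
#' table and the mapped regulation mode. Every link carries a defined mode;
#' rows with unmapped qualifiers never make it into a `RegulonSet`.
#'
#' @slot links data.frame with columns `regulator`, `gene`, `qualifier`,
#'   `mode` (`"up"`/`"down"`).
#' @seealso [readRegulonTable()], [regulonLinks()], [regulators()]
#' @export
setClass("RegulonSet", representation(links = "data.frame"))

setValidity("RegulonSet", function(object) {
  l <- object@links
  need <- c("regulator", "gene", "qualifier", "mode")
  if (!all(need %in% names(l)))
    return(paste("links must have columns:", paste(need, collapse = ", ")))
  if (nrow(l) && !all(l$mode %in% c("up", "down")))
    return("every link must have mode 'up' or 'down'")
  if (nrow(l) && (anyNA(l$regulator) || any(!nzchar(l$regulator))))
    return("regulator names must be non-empty")
  TRUE
})

#' Functional category annotation
#'
#' Gene-to-category links over a hierarchical classification
#' (main category / subcategory / sub-subcategory ...). A gene may appear
#' under several paths.
#'
#' @slot links data.frame with columns `gene`, `path` (the full path string)
#'   and list column `levels` (the path split into ordered levels).
#' @seealso [readCategoryTable()], [selectLevel()]
#' @export
setClass("CategorySet", representation(links = "data.frame"))

setValidity("CategorySet", function(object) {
  l <- object@links
  if (!all(c("gene", "path", "levels") %in% names(l)))
    return("links must have columns gene, path, levels")
  if (nrow(l) && !is.list(l$levels))
    return("levels must be a list column")
  if (nrow(l) && any(vapply(l$levels, length, 1L) == 0L))
    return("category paths must have at least one level")
  TRUE
})

#' Operon definitions
#'
#' Ordered member genes of each operon (transcription order preserved from
#' the source table). Singleton operons are allowed.
#'
#' @slot operons data.frame with column `operon_id` and list column `genes`.
#' @seealso [readOperonTable()], [buildOperonReport()]
#' @export
setClass("OperonSet", representation(operons = "data.frame"))

setValidity("OperonSet", function(object) {
  o <- object@operons
  if (!all(c("operon_id", "genes") %in% names(o)))
    return("operons must have columns operon_id, genes")
  if (nrow(o) && any(vapply(o$genes, length, 1L) < 1L))
    return("each operon needs at least one gene")
  if (anyDuplicated(o$operon_id))
    return("duplicated operon_id")
  TRUE
})

#' Regulon activity results
#'
#' Per-regulon results of the direction-aware analysis: inferred direction,
#' signed average fold change of the chosen gene group, its MAD, the
#' logical-regulation fraction, permutation P-value with BH adjustment and
#' the two classification schemes, plus the directionality-ignorant (raw)
#' score and MAD.
#'
#' @slot results data.frame, one row per scored regulon (see
#'   [scoreRegulons()] for the columns).
#' @slot skipped data.frame listing regulons excluded from scoring and why
#'   (below `minSize`, unmeasured, or uninformative).
#' @slot params list of analysis parameters (minSize, nPerm, seed,
#'   weightExponent, pvalueMode, exhaustive).
#' @seealso [scoreRegulons()], [activities()], [skippedRegulons()]
#' @export
setClass("RegulonActivity",
         representation(results = "data.frame", skipped = "data.frame",
                        params = "list"))

setValidity("RegulonActivity", function(object) {
  r <- object@results
  need <- c("regulator", "direction", "score", "mad", "n_total", "n_chosen",
            "logical_fraction", "pvalue", "padj", "raw_score", "raw_mad",
            "pclass", "fclass")
  if (!all(need %in% names(r)))
    return(paste("missing result columns:",
                 paste(setdiff(need, names(r)), collapse = ", ")))
  if (nrow(r)) {
    if (!all(r$direction %in% c("activated", "repressed", "ambiguous")))
      return("direction must be activated/repressed/ambiguous")
    if (any(r$n_chosen > r$n_total))
      return("n_chosen must not exceed n_total")
    bad <- r$direction != "ambiguous" & sign(r$score) != 0 &
      sign(r$score) != ifelse(r$direction == "activated", 1, -1)
    if (any(bad))
      return("sign of score must match direction")
  }
  TRUE
})
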