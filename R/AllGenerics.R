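#' @rdname RegulonSet-class
#' @param object,x a package object
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @rdname RegulonSet-class
#' @export
setGeneric("regulonLinks", function(x) standardGeneric("regulonLinks"))

#' @rdname CategorySet-class
#' @export
setGeneric("categoryLinks", function(x) standardGeneric("categoryLinks"))

#' @rdname OperonSet-class
#' @export
setGeneric("operonDefs", function(x) standardGeneric("operonDefs"))

#' @rdname RegulonActivity-class
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname RegulonActivity-class
#' @export
setGeneric("skippedRegulons", function(x) standardGeneric("skippedRegulons"))

#' @rdname RegulonActivity-class
#' @export
setGeneric("runParams", function(x) standardGeneric("runParams"))

setMethod("regulators", "RegulonSet",
          function(x) sort(unique(x@links$regulator)))

setMethod("regulonLinks", "RegulonSet", function(x) x@links)

setMethod("categoryLinks", "CategorySet", function(x) x@links)

setMethod("operonDefs", "OperonSet", function(x) x@operons)

setMethod("activities", "RegulonActivity", function(x) x@results)

setMethod("skippedRegulons", "RegulonActivity", function(x) x@skipped)

setMethod("runParams", "RegulonActivity", function(x) x@params)

#' @rdname RegulonActivity-class
#' @param row.names,optional,... passed on as in [base::as.data.frame()]
#' @export
setMethod("as.data.frame", "RegulonActivity",
          function(x, row.names = NULL, optional = FALSE, ...) x@results)

setMethod("show", "QualifierMap", function(object) {
  m <- object@map
  cat("QualifierMap with", length(m), "qualifiers\n")
  cat("  up:  ", paste(names(m)[m == "up"], collapse = ", "), "\n")
  cat("  down:", paste(names(m)[m == "down"], collapse = ", "), "\n")
})

setMethod("show", "RegulonSet", function(object) {
  l <- object@links
  cat("RegulonSet:", length(unique(l$regulator)), "regulators,",
      nrow(l), "links (", sum(l$mode == "up"), "up /",
      sum(l$mode == "down"), "down )\n")
})

setMethod("show", "CategorySet", function(object) {
  l <- object@links
  depth <- if (nrow(l)) max(vapply(l$levels, length, 1L)) else 0L
  cat("CategorySet:", length(unique(l$path)), "paths,", nrow(l),
      "gene links, max depth", depth, "\n")
})

setMethod("show", "OperonSet", function(object) {
  o <- object@operons
  sizes <- vapply(o$genes, length, 1L)
  cat("OperonSet:", nrow(o), "operons,",
      if (nrow(o)) paste0("sizes ", min(sizes), "-", max(sizes)) else "",
      "\n")
})

setMethod("show", "RegulonActivity", function(object) {
  r <- object@results
  cat("RegulonActivity:", nrow(r), "regulons scored (",
      sum(r$direction == "activated"), "activated,",
      sum(r$direction == "repressed"), "repressed,",
      sum(r$direction == "ambiguous"), "ambiguous ),",
      nrow(object@skipped), "skipped\n")
  cat("  params: minSize =", object@params$minSize,
      ", nPerm =", object@params$nPerm,
      ", seed =", object@params$seed,
      ", pvalueMode =", object@params$pvalueMode, "\n")
})
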