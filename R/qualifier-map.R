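#' Construct a qualifier map
#'
#' @param map named character vector mapping raw regulation qualifiers to
#'   `"up"` or `"down"`. Names are normalized (lowercase, trimmed, internal
#'   whitespace squeezed) so matching is case- and spacing-insensitive.
#' @return a [QualifierMap-class] object.
#' @examples
#' QualifierMap(c(Activation = "up", Repression = "down"))
#' @export
QualifierMap <- function(map) {
  stopifnot(is.character(map))
  names(map) <- .normalizeKey(names(map))
  new("QualifierMap", map = map)
}

#' Default qualifier map
#'
#' Covers the qualifiers commonly found in regulon annotation exports:
#' activation, antitermination, sigma factor(s) and positive regulation are
#' positive ("up") regulation — sigma factors direct RNA polymerase to their
#' target promoters and are therefore treated as positive regulators —
#' while repression and negative regulation are "down". Annotation databases
#' use further qualifiers; any qualifier absent from the map in use is a
#' hard error at read time, so extend or replace this map as needed.
#'
#' @return a [QualifierMap-class] object.
#' @export
defaultQualifierMap <- function() {
  QualifierMap(c(
    "activation"          = "up",
    "antitermination"     = "up",
    "sigma factor"        = "up",
    "sigma factors"       = "up",
    "positive regulation" = "up",
    "repression"          = "down",
    "negative regulation" = "down"
  ))
}

#' Read a qualifier map from file
#'
#' Accepts a two-column table (qualifier, mode) in TSV/CSV, or a
#' `key=value` config file (one `qualifier=mode` pair per line, `#`
#' comments allowed).
#'
#' @param path file path.
#' @param delim field delimiter; default sniffed from the extension
#'   (`=`-style files are detected automatically).
#' @return a [QualifierMap-class] object.
#' @export
readQualifierMap <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  body <- grep("^\\s*(#|$)", lines, invert = TRUE, value = TRUE)
  if (length(body) && all(grepl("=", body, fixed = TRUE))) {
    kv <- strsplit(body, "=", fixed = TRUE)
    map <- vapply(kv, function(p) trimws(paste(p[-1], collapse = "=")), "")
    names(map) <- vapply(kv, function(p) trimws(p[[1]]), "")
  } else {
    df <- .readTable(path, delim)
    if (ncol(df) < 2L)
      stop("qualifier map needs two columns (qualifier, mode)", call. = FALSE)
    map <- df[[2]]
    names(map) <- df[[1]]
  }
  map <- tolower(trimws(map))
  bad <- setdiff(unique(map), c("up", "down"))
  if (length(bad))
    stop("qualifier map modes must be 'up' or 'down', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  QualifierMap(map)
}
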