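# internal helpers shared across readers and scoring

# lowercase, trim, squeeze internal whitespace
.normalizeKey <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# delimiter from extension unless given explicitly
.sniffDelim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

.readTable <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = .sniffDelim(path, delim), header = TRUE,
                    quote = "\"", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "",
                    fileEncoding = "UTF-8")
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# Match gene names against a DE table: case-insensitive on gene name,
# falling back to the unique identifier. Returns row indices (NA = no match).
.matchGenes <- function(genes, de) {
  key <- .normalizeKey(genes)
  idx <- match(key, .normalizeKey(de$gene))
  if ("uid" %in% names(de)) {
    uidKey <- .normalizeKey(de$uid)
    uidKey[is.na(de$uid) | !nzchar(uidKey)] <- NA_character_
    miss <- is.na(idx)
    idx[miss] <- match(key[miss], uidKey)
  }
  idx
}

# run an expression with a private RNG state so callers' streams are untouched
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
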