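# Independent brute-force oracles, written directly from the definitions
# with plain loops. They share no code with the implementation they check.

# Direction-aware regulon evaluation: contributions, two groups, majority
# rule, mean-|contribution| tie rule.
bruteRegulon <- function(links, de) {
  act <- list(); rep_ <- list(); zero <- 0L
  for (i in seq_len(nrow(links))) {
    j <- which(tolower(de$gene) == tolower(links$gene[i]))
    if (length(j) == 0L && "uid" %in% names(de))
      j <- which(!is.na(de$uid) & tolower(de$uid) == tolower(links$gene[i]))
    if (length(j) == 0L) next
    fc <- de$log2fc[j[1]]
    contrib <- if (links$mode[i] == "down") -fc else fc
    if (contrib > 0) act[[length(act) + 1L]] <- contrib
    else if (contrib < 0) rep_[[length(rep_) + 1L]] <- contrib
    else zero <- zero + 1L
  }
  a <- unlist(act); r <- unlist(rep_)
  na <- length(a); nr <- length(r)
  if (na + nr == 0L) return(NULL)
  if (na > nr) { dir <- "activated"; chosen <- a }
  else if (nr > na) { dir <- "repressed"; chosen <- r }
  else if (mean(abs(a)) > mean(abs(r))) { dir <- "activated"; chosen <- a }
  else if (mean(abs(r)) > mean(abs(a))) { dir <- "repressed"; chosen <- r }
  else { dir <- "ambiguous"; chosen <- a }
  list(direction = dir, score = mean(chosen),
       n_chosen = length(chosen), n_total = na + nr + zero,
       logical_fraction = length(chosen) / (na + nr))
}

# Enrichment score by walking the full ranked list position by position.
naiveES <- function(stats, setPos, w = 1) {
  N <- length(stats); k <- length(setPos)
  tot <- sum(abs(stats[setPos])^w)
  running <- 0; best <- 0
  for (p in seq_len(N)) {
    if (p %in% setPos) {
      running <- running +
        (if (tot > 0) abs(stats[p])^w / tot else 1 / k)
    } else {
      running <- running - 1 / (N - k)
    }
    if (running > best) best <- running
  }
  min(max(best, 0), 1)
}

# random small regulon + DE table for oracle comparisons
randomRegulonCase <- function(maxGenes = 6L, nBackground = 4L) {
  n <- sample.int(maxGenes, 1L)
  genes <- paste0("g", seq_len(n + nBackground))
  de <- data.frame(gene = genes, uid = NA_character_,
                   log2fc = round(stats::rnorm(n + nBackground, 0, 2), 2),
                   pvalue = 0.5, padj = 0.5, stringsAsFactors = FALSE)
  links <- data.frame(gene = genes[seq_len(n)],
                      mode = sample(c("up", "down"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  list(links = links, de = de)
}

# small DE table used across tests
makeDE <- function(genes, fc, pvalue = rep(0.01, length(genes)),
                   padj = pvalue, uid = NA_character_) {
  data.frame(gene = genes, uid = uid, log2fc = fc, pvalue = pvalue,
             padj = padj, stringsAsFactors = FALSE)
}

makeLinks <- function(regulator, genes, modes) {
  data.frame(regulator = regulator, gene = genes,
             qualifier = ifelse(modes == "up", "activation", "repression"),
             mode = modes, stringsAsFactors = FALSE)
}

writeTmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
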