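#' Parameters for the synthetic benchmark generator
#'
#' Defines the study conditions emulated by [generateFixtures()]: a
#' background transcriptome with Gaussian log2 fold-change noise, a roster
#' of planted regulators whose targets are shifted by a known effect size,
#' a category hierarchy, and operons including one with a planted
#' discordant member.
#'
#' The default roster plants three activated and three repressed
#' regulators and three null regulators of 20 genes each at an effect size
#' of 2 log2 units over noise sd 0.3, plus one large mixed-mode regulator
#' ("SpoMix", 40 genes, half activation-type and half repression-type
#' links) emulating dual activator/repressors such as Spo0A, whose
#' directionality-ignorant average fold change is near zero even when the
#' regulator is strongly active. Some activated/repressed regulators have
#' all-repression link sets (`mixUp = 0`): these emulate pure repressors
#' like IolR, whose activation shows up as downregulated targets.
#'
#' @param nGenes number of genes in the DE table (default 1000).
#' @param delta planted effect size in log2 units (default 2).
#' @param sigma noise standard deviation in log2 units (default 0.3).
#' @param regulonSize genes per planted regulon (default 20).
#' @param mixedSize genes in the mixed-mode regulon (default 40).
#' @param aliasFraction fraction of regulon link rows that refer to the
#'   gene by its unique identifier (locus tag) instead of its name, to
#'   exercise the fallback matcher (default 0.05).
#' @return list of generator parameters including the regulator `roster`
#'   data.frame (`regulator`, `direction`, `size`, `mixUp`).
#' @export
fixtureParams <- function(nGenes = 1000L, delta = 2, sigma = 0.3,
                          regulonSize = 20L, mixedSize = 40L,
                          aliasFraction = 0.05) {
  stopifnot(delta >= 0, sigma >= 0, nGenes >= 1L, regulonSize >= 1L)
  roster <- data.frame(
    regulator = c("ActA1", "ActA2", "ActR1", "RepA1", "RepA2", "RepR1",
                  "NulA1", "NulR1", "NulM1", "SpoMix"),
    direction = c("activated", "activated", "activated",
                  "repressed", "repressed", "repressed",
                  "null", "null", "null", "activated"),
    size = c(rep(regulonSize, 9L), mixedSize),
    mixUp = c(1, 1, 0, 1, 1, 0, 1, 0, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
  if (sum(roster$size) + 60L > nGenes)
    stop("more regulon genes than genes: increase nGenes", call. = FALSE)
  list(nGenes = nGenes, delta = delta, sigma = sigma,
       regulonSize = regulonSize, mixedSize = mixedSize,
       aliasFraction = aliasFraction, roster = roster)
}

#' Generate synthetic input tables with planted ground truth
#'
#' Emulates the four input table shapes (DE results, regulon annotation,
#' functional categories, operons) with a known truth so the whole
#' pipeline is testable without any external data. Background genes draw
#' `log2fc ~ Normal(0, sigma)`; a planted activated regulator's
#' activation-type targets are shifted by `+delta` and its
#' repression-type targets by `-delta` (reversed for a repressed
#' regulator), so every informative target's signed contribution is
#' `+delta` (activated) or `-delta` (repressed) before noise. P-values
#' come from the known Gaussian model (two-sided z-test of `fc / sigma`),
#' not from a DE fit. One operon ("opDisc") is planted with a discordant
#' internal gene, one ("opUp") with strong concordant upregulation; one
#' gene is shared between two operons and one operon is a singleton.
#'
#' Regeneration with the same `params` and `seed` is deterministic, and
#' written tables are byte-identical across runs.
#'
#' @param params from [fixtureParams()].
#' @param seed integer RNG seed.
#' @param outDir if non-`NULL`, write `de.tsv`, `regulons.tsv`,
#'   `categories.tsv`, `operons.tsv` and `truth.tsv` there.
#' @return list with elements `de` (DE data.frame), `regulons`
#'   ([RegulonSet-class]), `categories` ([CategorySet-class]), `operons`
#'   ([OperonSet-class]), `truth` (list: `roster`, planted operon genes),
#'   and `tables` (the raw data.frames as written).
#' @export
generateFixtures <- function(params = fixtureParams(), seed = 1L,
                             outDir = NULL) {
  .withSeed(seed, {
    n <- params$nGenes
    gene <- sprintf("g%04d", seq_len(n))
    uid <- sprintf("BSU%05d", seq_len(n) * 10L)
    fc <- stats::rnorm(n, 0, params$sigma)

    roster <- params$roster
    # disjoint target blocks from the front of the gene list
    offsets <- cumsum(c(0L, roster$size))
    linkRows <- list()
    for (i in seq_len(nrow(roster))) {
      targets <- (offsets[i] + 1L):offsets[i + 1L]
      nUp <- round(roster$mixUp[i] * length(targets))
      mode <- rep("down", length(targets))
      if (nUp > 0L) mode[seq_len(nUp)] <- "up"
      shift <- switch(roster$direction[i],
        activated = params$delta * ifelse(mode == "up", 1, -1),
        repressed = -params$delta * ifelse(mode == "up", 1, -1),
        null = 0)
      fc[targets] <- fc[targets] + shift
      qualifier <- ifelse(mode == "up",
        sample(c("activation", "sigma factor", "positive regulation",
                 "antitermination"), length(targets), replace = TRUE),
        sample(c("repression", "negative regulation"), length(targets),
               replace = TRUE))
      linkRows[[i]] <- data.frame(regulator = roster$regulator[i],
                                  gene = gene[targets],
                                  qualifier = qualifier,
                                  stringsAsFactors = FALSE)
    }
    links <- do.call(rbind, linkRows)
    # a few link rows use the locus tag instead of the gene name
    nAlias <- floor(params$aliasFraction * nrow(links))
    if (nAlias > 0L) {
      ali <- sort(sample.int(nrow(links), nAlias))
      links$gene[ali] <- uid[match(links$gene[ali], gene)]
    }

    # planted operons live in the untouched background tail
    tail0 <- n - 59L
    opGenes <- function(k, len) gene[(tail0 + k):(tail0 + k + len - 1L)]
    discGenes <- opGenes(0L, 2L)
    upGenes <- opGenes(2L, 2L)
    fc[match(discGenes, gene)] <- c(params$delta, -params$delta)
    fc[match(upGenes, gene)] <- c(params$delta, params$delta)
    operonDf <- data.frame(
      operon = c("opDisc", "opUp", "opShared1", "opShared2", "opSingle",
                 sprintf("opBg%02d", 1:10)),
      genes = c(paste(discGenes, collapse = ";"),
                paste(upGenes, collapse = ";"),
                paste(opGenes(4L, 3L), collapse = ";"),
                # first gene shared with opShared1
                paste(gene[c(tail0 + 6L, tail0 + 7L, tail0 + 8L)],
                      collapse = ";"),
                gene[tail0 + 9L],
                vapply(1:10, function(k)
                  paste(opGenes(9L + 3L * k, 3L), collapse = ";"), "")),
      stringsAsFactors = FALSE)

    # category hierarchy: 3 main x 3 sub x 2 leaves, deterministic by index
    mains <- c("Metabolism", "Cell envelope", "Stress response")
    subs <- paste0("Sub", 1:3)
    leaves <- paste0("Leaf", 1:2)
    path <- paste(mains[(seq_len(n) - 1L) %% 3L + 1L],
                  subs[((seq_len(n) - 1L) %/% 3L) %% 3L + 1L],
                  leaves[((seq_len(n) - 1L) %/% 9L) %% 2L + 1L],
                  sep = ".")
    catDf <- data.frame(gene = gene, category = path,
                        stringsAsFactors = FALSE)
    # a handful of genes under a second path, and two shallow paths
    extra <- data.frame(gene = gene[1:5],
                        category = paste("Stress response", "SubX",
                                         sep = "."),
                        stringsAsFactors = FALSE)
    shallow <- data.frame(gene = gene[6:7], category = "Metabolism",
                          stringsAsFactors = FALSE)
    catDf <- rbind(catDf, extra, shallow)

    sigma <- params$sigma
    pvalue <- if (sigma > 0) 2 * stats::pnorm(-abs(fc) / sigma) else
      ifelse(fc == 0, 1, 0)
    deDf <- data.frame(gene = gene, uid = uid,
                       log2FC = fc, pvalue = pvalue,
                       padj = bhAdjust(pvalue), stringsAsFactors = FALSE)

    de <- data.frame(gene = gene, uid = uid, log2fc = fc, pvalue = pvalue,
                     padj = deDf$padj, stringsAsFactors = FALSE)
    attr(de, "load_report") <- list(total = n, parsed = n, dropped = 0L)

    catLinks <- data.frame(gene = catDf$gene, path = catDf$category,
                           stringsAsFactors = FALSE)
    catLinks$levels <- strsplit(catDf$category, ".", fixed = TRUE)
    opsDefs <- data.frame(operon_id = operonDf$operon,
                          stringsAsFactors = FALSE)
    opsDefs$genes <- strsplit(operonDf$genes, ";", fixed = TRUE)

    truth <- list(roster = roster, delta = params$delta,
                  sigma = params$sigma,
                  discordant_operon = "opDisc",
                  discordant_genes = discGenes,
                  concordant_operon = "opUp", seed = seed)
    truthDf <- roster
    truthDf$delta <- params$delta
    truthDf$sigma <- params$sigma
    truthDf$seed <- seed

    tables <- list(de = deDf, regulons = links, categories = catDf,
                   operons = operonDf, truth = truthDf)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeReportTable(deDf, file.path(outDir, "de.tsv"))
      writeReportTable(links, file.path(outDir, "regulons.tsv"))
      writeReportTable(catDf, file.path(outDir, "categories.tsv"))
      writeReportTable(operonDf, file.path(outDir, "operons.tsv"))
      writeReportTable(truthDf, file.path(outDir, "truth.tsv"))
    }
    list(de = de,
         regulons = RegulonSet(links),
         categories = new("CategorySet", links = catLinks),
         operons = new("OperonSet", operons = opsDefs),
         truth = truth,
         tables = tables)
  })
}
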