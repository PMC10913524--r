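test_that("signed contributions encode consistency with regulator activity", {
  # a repressed target downregulated 2.03-fold supports an active repressor
  expect_equal(signedContribution(-2.03, "down"), 2.03)
  expect_equal(signedContribution(1.5, "up"), 1.5)
  expect_equal(signedContribution(0, "down"), 0)
  expect_equal(signedContribution(c(1, -1), c("up", "down")), c(1, 1))
})

test_that("madFC is the unscaled median absolute deviation", {
  expect_equal(madFC(c(1, 2, 6)), 1)          # median 2, deviations 1,0,4
  expect_equal(madFC(rep(3.7, 5)), 0)
  expect_error(madFC(numeric(0)), "empty")
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rnorm(sample(1:30, 1))
    a <- stats::runif(1, -3, 3); b <- stats::runif(1, -3, 3)
    expect_equal(madFC(-x), madFC(x))
    expect_equal(madFC(a * x + b), abs(a) * madFC(x))
  }
})

test_that("splitRegulon partitions genes by contribution sign", {
  de <- makeDE(c("a", "b", "c", "d"), c(2, 1, -1, 0.5))
  links <- makeLinks("R", c("a", "b", "c", "d"),
                     c("up", "up", "down", "down"))
  sp <- splitRegulon(links, de)
  expect_setequal(sp$active$gene, c("a", "b", "c"))
  expect_equal(sp$repressed$gene, "d")
  expect_length(sp$zero, 0L)
  expect_equal(nrow(sp$active) + nrow(sp$repressed) + length(sp$zero),
               sp$n_measured)

  deZero <- makeDE(c("a", "b"), c(0, 0))
  sp0 <- splitRegulon(makeLinks("R", c("a", "b"), c("up", "down")), deZero)
  expect_equal(nrow(sp0$active), 0L)
  expect_equal(nrow(sp0$repressed), 0L)
  expect_setequal(sp0$zero, c("a", "b"))

  # repressor-only regulon, all targets down => all support activation
  deRep <- makeDE(c("x", "y"), c(-1, -2))
  spR <- splitRegulon(makeLinks("R", c("x", "y"), c("down", "down")), deRep)
  expect_equal(nrow(spR$repressed), 0L)
  expect_equal(nrow(spR$active), 2L)
})

test_that("chooseGroup applies majority, magnitude tie rule, ambiguity", {
  de <- makeDE(c("a", "b", "c", "d"), c(2, 1, -1, 0.5))
  sp <- splitRegulon(makeLinks("R", c("a", "b", "c", "d"),
                               c("up", "up", "down", "down")), de)
  ch <- chooseGroup(sp)
  expect_equal(ch$direction, "activated")
  expect_equal(nrow(ch$chosen), 3L)

  # tie on size: the group with higher mean |contribution| wins
  deT <- makeDE(c("a", "b"), c(3, -1))
  chT <- chooseGroup(splitRegulon(makeLinks("R", c("a", "b"),
                                            c("up", "up")), deT))
  expect_equal(chT$direction, "activated")
  deT2 <- makeDE(c("a", "b"), c(1, -3))
  chT2 <- chooseGroup(splitRegulon(makeLinks("R", c("a", "b"),
                                             c("up", "up")), deT2))
  expect_equal(chT2$direction, "repressed")

  # double tie => ambiguous
  deA <- makeDE(c("a", "b"), c(2, -2))
  chA <- chooseGroup(splitRegulon(makeLinks("R", c("a", "b"),
                                            c("up", "up")), deA))
  expect_equal(chA$direction, "ambiguous")

  deZ <- makeDE(c("a", "b"), c(0, 0))
  expect_error(chooseGroup(splitRegulon(makeLinks("R", c("a", "b"),
                                                  c("up", "down")), deZ)),
               "no informative genes")
})

test_that("scoreRegulon evaluates the worked examples", {
  de <- makeDE(c("a", "b", "c", "d"), c(2, 1, -1, 0.5))
  links <- makeLinks("R", c("a", "b", "c", "d"),
                     c("up", "up", "down", "down"))
  sc <- scoreRegulon("R", links, de)
  expect_equal(sc$direction, "activated")
  expect_equal(sc$score, mean(c(2, 1, 1)))
  expect_equal(sc$logical_fraction, 3 / 4)
  expect_equal(sc$n_total, 4L)
  expect_equal(sc$n_chosen, 3L)

  # pure repressor with all targets down: positive score (active repressor)
  deR <- makeDE(c("x", "y", "z"), c(-1, -2, -3))
  scR <- scoreRegulon("R", makeLinks("R", c("x", "y", "z"),
                                     rep("down", 3)), deR)
  expect_equal(scR$direction, "activated")
  expect_equal(scR$score, 2)
  expect_equal(scR$logical_fraction, 1)
  expect_equal(scR$raw_score, -2)       # directionality-ignorant mean
  expect_equal(scR$raw_mad, 1)
})

test_that("regulons below minSize, unmeasured or uninformative are skipped", {
  de <- makeDE(c("a", "b"), c(1, 2))
  one <- scoreRegulon("R", makeLinks("R", "a", "up"), de)
  expect_s3_class(one, "regdir_skip")
  expect_equal(attr(one, "reason"), "below_min_size")
  unm <- scoreRegulon("R", makeLinks("R", c("q", "w"), c("up", "up")), de)
  expect_equal(attr(unm, "reason"), "unmeasured")
  deZ <- makeDE(c("a", "b"), c(0, 0))
  zz <- scoreRegulon("R", makeLinks("R", c("a", "b"), c("up", "down")), deZ)
  expect_equal(attr(zz, "reason"), "uninformative")
})

test_that("scoring matches the brute-force oracle on random small regulons", {
  set.seed(7)
  for (i in 1:100) {
    cs <- randomRegulonCase()
    sc <- scoreRegulon("R", cs$links, cs$de, minSize = 1L)
    oracle <- bruteRegulon(cs$links, cs$de)
    if (is.null(oracle)) {
      expect_s3_class(sc, "regdir_skip")
      next
    }
    expect_equal(sc$direction, oracle$direction)
    expect_equal(sc$score, oracle$score)
    expect_equal(sc$n_chosen, oracle$n_chosen)
    expect_equal(sc$n_total, oracle$n_total)
    expect_equal(sc$logical_fraction, oracle$logical_fraction)
  }
})

test_that("sign-flip equivariance and mode-duality hold", {
  set.seed(11)
  for (i in 1:25) {
    cs <- randomRegulonCase(maxGenes = 6L)
    sc <- scoreRegulon("R", cs$links, cs$de, minSize = 1L)
    deNeg <- cs$de; deNeg$log2fc <- -deNeg$log2fc
    scNeg <- scoreRegulon("R", cs$links, deNeg, minSize = 1L)
    if (inherits(sc, "regdir_skip")) next
    flip <- c(activated = "repressed", repressed = "activated",
              ambiguous = "ambiguous")
    expect_equal(scNeg$direction, unname(flip[sc$direction]))
    expect_equal(scNeg$score, -sc$score)
    expect_equal(scNeg$mad, sc$mad)
    expect_equal(scNeg$n_chosen, sc$n_chosen)
    expect_equal(scNeg$logical_fraction, sc$logical_fraction)

    # all-down links on x behave like all-up links on -x
    linksDown <- cs$links; linksDown$mode <- "down"
    linksUp <- cs$links; linksUp$mode <- "up"
    a <- scoreRegulon("R", linksDown, cs$de, minSize = 1L)
    b <- scoreRegulon("R", linksUp, deNeg, minSize = 1L)
    if (!inherits(a, "regdir_skip")) {
      expect_equal(a$direction, b$direction)
      expect_equal(a$score, b$score)
      expect_equal(a$logical_fraction, b$logical_fraction)
    }
  }
})

test_that("logical fraction is always at least one half", {
  set.seed(13)
  for (i in 1:50) {
    cs <- randomRegulonCase()
    sc <- scoreRegulon("R", cs$links, cs$de, minSize = 1L)
    if (inherits(sc, "regdir_skip")) next
    expect_gte(sc$logical_fraction, 0.5)
    expect_lte(sc$logical_fraction, 1)
  }
})

test_that("batch scoring returns a valid RegulonActivity with classes", {
  fx <- generateFixtures(fixtureParams(nGenes = 300), seed = 3)
  act <- scoreRegulons(fx$de, fx$regulons, nPerm = 200, seed = 3)
  expect_s4_class(act, "RegulonActivity")
  res <- activities(act)
  expect_true(all(res$padj >= res$pvalue))
  expect_true(all(res$n_chosen <= res$n_total))
  expect_true(all(res$pclass %in% 1:5))
  expect_true(validObject(act))
  # uid-aliased annotation rows all resolved through the fallback matcher
  expect_length(attr(act, "unmatched_genes"), 0L)
})
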