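test_that("rankedList sorts descending with name tie-breaking", {
  r <- rankedList(c("b", "a", "c"), c(1, 2, 1))
  expect_equal(r$genes, c("a", "b", "c"))
  expect_equal(r$stats, c(2, 1, 1))
  # input order never matters
  r2 <- rankedList(c("c", "b", "a"), c(1, 1, 2))
  expect_identical(r, r2)
})

test_that("enrichment score reproduces the running-sum worked examples", {
  r <- rankedList(paste0("g", 1:5), c(3, 2, 1, -1, -2))
  expect_equal(enrichmentScore(r, c("g1", "g2")), 1.0)
  expect_equal(enrichmentScore(r, c("g1", "g3")), 0.75)
  expect_equal(enrichmentScore(r, r$genes), 1.0)   # whole list
  expect_error(enrichmentScore(r, "absent"), "unmeasured")
})

test_that("enrichment score matches the naive walk for all sets, N <= 8", {
  set.seed(5)
  stats <- round(stats::rnorm(8, 0, 2), 2)
  r <- rankedList(paste0("g", 1:8), stats)
  for (k in 1:8) {
    sets <- utils::combn(8, k)
    for (j in seq_len(ncol(sets))) {
      pos <- sets[, j]
      expect_equal(enrichmentScore(r, r$genes[pos]),
                   naiveES(r$stats, pos),
                   info = paste("k =", k, "set", j))
    }
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  library(fgsea)
  set.seed(9)
  for (i in 1:20) {
    stats <- sort(stats::rnorm(30, 0, 2), decreasing = TRUE)
    r <- rankedList(paste0("g", sprintf("%02d", 1:30)), stats)
    # positions biased to the top so the positive deviation dominates and
    # both conventions measure the same quantity
    pos <- sort(sample.int(12, 5))
    ours <- enrichmentScore(r, r$genes[pos])
    theirs <- fgsea::calcGseaStat(stats, selectedStats = pos, gseaParam = 1)
    if (theirs > 0) expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("rank-only scoring ignores monotone transforms of the statistic", {
  set.seed(21)
  stats <- sort(stats::rnorm(20), decreasing = TRUE)
  r1 <- rankedList(paste0("g", sprintf("%02d", 1:20)), stats)
  r2 <- rankedList(r1$genes, 10 * stats + 100)  # order-preserving
  set <- r1$genes[c(2, 5, 11)]
  expect_equal(enrichmentScore(r1, set, weightExponent = 0),
               enrichmentScore(r2, set, weightExponent = 0))
})

test_that("exhaustive permutation p equals the enumerated fraction", {
  r <- rankedList(paste0("g", 1:5), c(3, 2, 1, -1, -2))
  p <- permutationPValue(r, c("g1", "g2"), exhaustive = TRUE)
  expect_equal(p, 2 / 11)   # only the observed set reaches ES = 1 among C(5,2)
  # observed ES at the null minimum gives p = 1
  pMin <- permutationPValue(r, c("g4", "g5"), exhaustive = TRUE)
  expect_equal(pMin, 1)
})

test_that("sampled p is deterministic under a fixed seed and converges", {
  r <- rankedList(paste0("g", 1:5), c(3, 2, 1, -1, -2))
  p1 <- permutationPValue(r, c("g1", "g2"), nPerm = 500, seed = 42)
  p2 <- permutationPValue(r, c("g1", "g2"), nPerm = 500, seed = 42)
  expect_identical(p1, p2)
  # the sampled estimator converges to the exhaustive exceedance fraction
  # (the plus-one corrections differ at C(5,2) = 10 enumerable sets, so the
  # comparison is on the underlying fraction both estimate)
  obs <- enrichmentScore(r, c("g1", "g2"))
  allES <- apply(utils::combn(5, 2), 2, function(pos) naiveES(r$stats, pos))
  exceed <- mean(allES >= obs - 1e-12)
  pHat <- permutationPValue(r, c("g1", "g2"), nPerm = 10000, seed = 1)
  expect_lt(abs(pHat - exceed), 0.02)
})

test_that("BH adjustment reproduces the step-up example and its laws", {
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bhAdjust(1), 1)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:10) {
    p <- stats::runif(sample(1:50, 1))
    adj <- bhAdjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # ranking preserved
  }
})

test_that("P-value quantile classes follow the 10/20/33/50 scheme", {
  padj <- seq(0.01, 0.10, by = 0.01)
  cls <- pvalueQuantileClass(padj, paste0("r", 1:10))
  expect_equal(cls, c(1L, 2L, 3L, 3L, 4L, 5L, 5L, 5L, 5L, 5L))
  expect_equal(pvalueQuantileClass(0.5, "only"), 1L)
  for (N in c(1:20, 199, 200)) {
    cls <- pvalueQuantileClass(stats::runif(N))
    expect_true(all(cls %in% 1:5))
    expect_equal(sum(cls == 1), ceiling(0.1 * N))
  }
})

test_that("fraction classes use lower-inclusive boundaries", {
  expect_equal(fractionClass(0.95), 1L)
  expect_equal(fractionClass(0.90), 1L)
  expect_equal(fractionClass(0.80), 2L)
  expect_equal(fractionClass(0.75), 3L)
  expect_equal(fractionClass(0.67), 4L)
  expect_equal(fractionClass(0.50), 5L)
  expect_equal(fractionClass(0.66), 5L)
  expect_true(is.na(fractionClass(0.49)))
})

test_that("consistent regulons outscore inconsistent ones of equal size", {
  # on the synthetic benchmark, every planted direction-consistent regulon
  # (all contributions the same sign, magnitude delta) must attain a
  # smaller p than every null regulon of the same size, whose
  # contributions are direction-inconsistent noise
  fx <- generateFixtures(seed = 17)
  act <- scoreRegulons(fx$de, fx$regulons, nPerm = 2000, seed = 17)
  res <- activities(act)
  truth <- fx$truth$roster
  size20 <- truth$regulator[truth$size == 20]
  isNull <- truth$direction[match(res$regulator, truth$regulator)] == "null"
  planted <- res$pvalue[!isNull & res$regulator %in% size20]
  nulls <- res$pvalue[isNull & res$regulator %in% size20]
  expect_lt(max(planted), min(nulls))
})
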