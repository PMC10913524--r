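test_that("DE reader parses well-formed tables and accounts for drops", {
  path <- writeTmp(c("gene\tlog2FC\tpvalue",
                     "iolA\t-2.03\t0.001",
                     "ydaP\t1.20\t0.01",
                     "pgi\t0.05\t0.8"))
  de <- readDETable(path)
  expect_equal(nrow(de), 3L)
  expect_equal(loadReport(de),
               list(total = 3L, parsed = 3L, dropped = 0L))
  expect_equal(de$log2fc[de$gene == "iolA"], -2.03)

  path2 <- writeTmp(c("gene\tlog2FC\tpvalue",
                      "iolA\t-2.03\t0.001",
                      "ydaP\tNA\t0.01",
                      "pgi\t0.05\t0.8"))
  de2 <- readDETable(path2)
  expect_equal(nrow(de2), 2L)
  expect_equal(loadReport(de2)$dropped, 1L)
  expect_equal(loadReport(de2)$parsed + loadReport(de2)$dropped,
               loadReport(de2)$total)
})

test_that("DE reader errors name the offending column or duplicate", {
  noGene <- writeTmp(c("id\tlog2FC", "x\t1.0"))
  expect_error(readDETable(noGene), "gene")
  dup <- writeTmp(c("gene\tlog2FC", "iolA\t1.0", "IolA\t2.0"))
  expect_error(readDETable(dup), "iolA|IolA")
  badP <- writeTmp(c("gene\tlog2FC\tpvalue", "a\t1\t1.5"))
  expect_error(readDETable(badP), "pvalue")
})

test_that("delimiter is sniffed from the extension and overridable", {
  csv <- writeTmp(c("gene,log2FC", "a,1.5", "b,-0.5"), ext = ".csv")
  de <- readDETable(csv)
  expect_equal(de$log2fc, c(1.5, -0.5))
  odd <- writeTmp(c("gene;log2FC", "a;2.0"), ext = ".txt")
  de2 <- readDETable(odd, delim = ";")
  expect_equal(de2$log2fc, 2.0)
})

test_that("regulon qualifiers map case-insensitively to modes", {
  path <- writeTmp(c("regulator\tgene\tqualifier",
                     "SigB\tydaP\tsigma factor",
                     "IolR\tiolA\tRepression",
                     "AbrB\tabn2\t Activation "))
  rs <- readRegulonTable(path)
  links <- regulonLinks(rs)
  expect_equal(links$mode[links$regulator == "SigB"], "up")
  expect_equal(links$mode[links$regulator == "IolR"], "down")
  expect_equal(links$mode[links$regulator == "AbrB"], "up")
})

test_that("unmapped qualifiers are a hard error listing them all", {
  path <- writeTmp(c("regulator\tgene\tqualifier",
                     "X\tg1\tmystery-qualifier",
                     "Y\tg2\tanother-one",
                     "Z\tg3\tactivation"))
  err <- expect_error(readRegulonTable(path), "mystery-qualifier")
  expect_match(conditionMessage(err), "another-one")
})

test_that("conflicting duplicate links keep the first mode with a warning", {
  path <- writeTmp(c("regulator\tgene\tqualifier",
                     "R\tg1\tactivation",
                     "R\tg1\trepression"))
  expect_warning(rs <- readRegulonTable(path), "conflicting")
  links <- regulonLinks(rs)
  expect_equal(nrow(links), 1L)
  expect_equal(links$mode, "up")
})

test_that("qualifier maps load from key=value and two-column files", {
  kv <- writeTmp(c("# custom map", "Activation = up",
                   "strange-mode=down"), ext = ".cfg")
  qm <- readQualifierMap(kv)
  expect_equal(unname(qm@map["strange-mode"]), "down")
  tsv <- writeTmp(c("qualifier\tmode", "activation\tup",
                    "silencing\tdown"))
  qm2 <- readQualifierMap(tsv)
  expect_equal(unname(qm2@map["silencing"]), "down")
  bad <- writeTmp(c("qualifier\tmode", "activation\tsideways"))
  expect_error(readQualifierMap(bad), "sideways")
})

test_that("category paths split into ordered levels", {
  path <- writeTmp(c("gene\tcategory",
                     "pgi\tMetabolism.Carbon metabolism.Glycolysis",
                     "pgi\tStress response.General",
                     "yoxA\t"))
  cs <- readCategoryTable(path)
  links <- categoryLinks(cs)
  expect_equal(nrow(links), 2L)   # empty path excluded
  expect_equal(loadReport(cs)$dropped, 1L)
  expect_equal(links$levels[[1]],
               c("Metabolism", "Carbon metabolism", "Glycolysis"))
  expect_equal(sum(links$gene == "pgi"), 2L)  # one gene, two paths
})

test_that("operon reader preserves gene order in both layouts", {
  wide <- writeTmp(c("operon\tgenes",
                     "yxaJ-yxaL\tyxaJ;yxaL",
                     "solo\tydaP",
                     "empty\t"))
  os <- readOperonTable(wide)
  defs <- operonDefs(os)
  expect_equal(nrow(defs), 2L)
  expect_equal(defs$genes[[which(defs$operon_id == "yxaJ-yxaL")]],
               c("yxaJ", "yxaL"))
  expect_equal(loadReport(os)$dropped, 1L)

  long <- writeTmp(c("operon\tgene\tposition",
                     "opA\tb2\t2", "opA\tb1\t1", "opA\tb3\t3"))
  os2 <- readOperonTable(long)
  expect_equal(operonDefs(os2)$genes[[1]], c("b1", "b2", "b3"))
})

test_that("report tables round-trip through write/read", {
  df <- data.frame(name = c("a b", "c"), n = c(1L, 2L),
                   x = c(1 / 3, -2.034561278341e-7),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeReportTable(df, path)
  back <- readReportTable(path)
  expect_identical(back$name, df$name)
  expect_identical(back$n, df$n)
  expect_true(all(abs(back$x - df$x) < 1e-12))
})
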