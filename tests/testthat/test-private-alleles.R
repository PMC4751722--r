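test_that("allele classification is exhaustive and mutually exclusive", {
  expect_equal(classifyAllele(180, c(180, 184), c(184, 196)), "DAM_PRIVATE")
  expect_equal(classifyAllele(184, c(180, 184), c(184, 196)), "SHARED")
  expect_equal(classifyAllele(196, c(180, 184), c(184, 196)), "SIRE_PRIVATE")
  expect_equal(classifyAllele(210, c(180, 184), c(184, 196)), "NON_PARENTAL")
  expect_error(classifyAllele(180, integer(0), 184), "non-empty")

  set.seed(121)
  for (i in 1:20) {
    dam <- sample(100:140, 5); sire <- sample(100:140, 5)
    cls <- classifyAllele(100:140, dam, sire)
    expect_true(all(cls %in% c("DAM_PRIVATE", "SIRE_PRIVATE", "SHARED",
                               "NON_PARENTAL")))
    expect_equal(cls == "DAM_PRIVATE", 100:140 %in% setdiff(dam, sire))
    expect_equal(cls == "SHARED", 100:140 %in% intersect(dam, sire))
  }
})

test_that("private-allele counting scores distinct private alleles only", {
  tab <- toyCrossTable()
  expect_message(
    mat <- countPrivateAlleles(tab, list(g1 = "kid1", g2 = "kid2")),
    "uninformative")
  # L3 (parents identical) is excluded
  expect_equal(loci(mat), c("L1", "L2"))
  ic <- mat@individualCounts
  # kid1 at L1 = {180,184}: only 180 is dam-unique
  expect_equal(ic$count[ic$sample_id == "kid1" & ic$locus == "L1" &
                          ic$parent == "DAM"], 1L)
  expect_equal(ic$count[ic$sample_id == "kid1" & ic$locus == "L1" &
                          ic$parent == "SIRE"], 0L)
  # kid2 at L1 equals the sire set
  expect_equal(ic$count[ic$sample_id == "kid2" & ic$locus == "L1" &
                          ic$parent == "SIRE"], 1L)

  # kid2 at L2 = {304, 324}: one allele private to each parent
  expect_equal(ic$count[ic$sample_id == "kid2" & ic$locus == "L2" &
                          ic$parent == "DAM"], 1L)
  expect_equal(ic$count[ic$sample_id == "kid2" & ic$locus == "L2" &
                          ic$parent == "SIRE"], 1L)

  # offspring set equal to the sire set, fully disjoint parents
  disj <- GenotypeTable(
    samples = data.frame(sample_id = c("d", "s", "k"),
                         role = c("DAM", "SIRE", "OFFSPRING")),
    genotypes = data.frame(
      sample_id = c("d", "d", "s", "s", "k", "k"),
      locus = "L1",
      allele = c(100L, 104L, 200L, 204L, 200L, 204L)))
  md <- cpa(disj, list(g = "k"))
  expect_equal(unname(groupTotals(md, "DAM")), 0)
  expect_equal(unname(groupTotals(md, "SIRE")), 2)

  expect_error(cpa(tab, list(g = "ghost")), "absent")
})

test_that("counts decompose the observed set size by allele class", {
  sim <- simulateMixedCross(CrossConfig(femaleModel = "PB2_RETENTION",
                                        seed = 131), 5, 5)
  tab <- sim$table
  dam <- damId(tab); sire <- sireId(tab)
  for (id in offspringIds(tab)) {
    for (l in loci(tab)) {
      obs <- alleleSet(tab, id, l)
      if (!length(obs)) next
      cls <- classifyAllele(obs, alleleSet(tab, dam, l),
                            alleleSet(tab, sire, l))
      expect_equal(sum(table(cls)), length(obs))
    }
  }
})

test_that("clonal offspring recover the dam's own private-allele counts", {
  sim <- simulateCross(CrossConfig(femaleModel = "APOMIXIS_CLONE",
                                   nOffspring = 4, observationDropout = 0,
                                   seed = 141))
  tab <- sim$table
  groups <- list(clones = offspringIds(tab))
  mat <- cpa(tab, groups)
  dam <- damId(tab); sire <- sireId(tab)
  ic <- mat@individualCounts
  for (l in loci(mat)) {
    damPrivate <- setdiff(alleleSet(tab, dam, l), alleleSet(tab, sire, l))
    perKid <- ic$count[ic$locus == l & ic$parent == "DAM"]
    # sire gametes may add alleles but never remove the dam's private set
    expect_true(all(perKid == length(damPrivate)))
  }
})

test_that("the paired t statistic matches its closed form and symmetry", {
  r0 <- pairedT(rep(2, 8), rep(2, 8))
  expect_equal(r0@t, 0)
  expect_equal(r0@p, 1)
  expect_equal(r0@df, 7L)

  r <- pairedT(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r@t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r@df, 2L)
  expect_equal(r@meanDiff, 2)

  # antisymmetry: swapping the series negates t, preserves p
  a <- c(3, 5, 2, 8, 1); b <- c(4, 4, 6, 9, 0)
  expect_equal(pairedT(a, b)@t, -pairedT(b, a)@t)
  expect_equal(pairedT(a, b)@p, pairedT(b, a)@p)

  # zero variance with non-zero mean is degenerate
  dg <- pairedT(c(1, 1, 1), c(3, 3, 3))
  expect_true(dg@degenerate)
  expect_equal(dg@t, Inf)
  expect_equal(dg@p, 0)

  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("normality screening handles degenerate and regular input", {
  expect_warning(p <- shapiroWilkCheck(c(2, 2, 2)), "constant")
  expect_true(is.na(p))
  expect_warning(p2 <- shapiroWilkCheck(c(1, 2)), "at least 3")
  expect_true(is.na(p2))

  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  ref <- shapiro.test(x)
  got <- shapiroWilkCheck(x)
  expect_equal(as.numeric(got), unname(ref$p.value), tolerance = 1e-3)
  expect_equal(attr(got, "W"), unname(ref$statistic), tolerance = 1e-3)

  set.seed(151)
  expect_gt(shapiroWilkCheck(rnorm(100)), 0.001)
})

test_that("fold change is the ratio of group totals", {
  mat <- readCountMatrix(system.file("extdata", "synthetic_s1_counts.tsv",
                                     package = "ploidyOrigin"))
  expect_equal(foldChange(mat, "DAM", "7n", "5n"), 63 / 35)
  expect_equal(foldChange(mat, "DAM", "7n", "5n", digits = 1), 1.8)
  expect_equal(foldChange(mat, "DAM", "5n", "5n"), 1)
  expect_equal(foldChange(mat, "SIRE", "7n", "5n"), 1)

  zero <- new("PrivateAlleleMatrix", loci = "L1",
              groups = list(a = character(0), b = character(0)),
              counts = data.frame(locus = "L1", group = c("a", "b"),
                                  parent = "DAM", count = c(3L, 0L)),
              individualCounts = mat@individualCounts[0, ])
  expect_warning(fc <- foldChange(zero, "DAM", "a", "b"), "undefined")
  expect_true(is.nan(fc))
})

test_that("hypothesis battery requires a directional, significant increase", {
  mkmat <- function(ref, test, sref = rep(2L, 8), stest = rep(2L, 8)) {
    lc <- sprintf("L%02d", 1:8)
    new("PrivateAlleleMatrix", loci = lc,
        groups = list(ref = character(0), test = character(0)),
        counts = data.frame(
          locus = rep(lc, 4),
          group = rep(c("ref", "test", "ref", "test"), each = 8),
          parent = rep(c("DAM", "DAM", "SIRE", "SIRE"), each = 8),
          count = as.integer(c(ref, test, sref, stest))),
        individualCounts = data.frame(
          sample_id = character(0), group = character(0),
          locus = character(0), parent = character(0), count = integer(0)))
  }
  up <- mkmat(ref = rep(4L, 8), test = c(7L, 8L, 7L, 8L, 7L, 8L, 7L, 8L))
  hyp <- suppressWarnings(testHypotheses(up))
  expect_true(hyp$supported[hyp$hypothesis == "H1_DAM"])
  expect_false(hyp$supported[hyp$hypothesis == "H2_SIRE"])
  expect_false(hyp$supported[hyp$hypothesis == "H3_BOTH"])

  # identical groups support nothing
  flat <- mkmat(ref = rep(4L, 8), test = rep(4L, 8))
  expect_false(any(testHypotheses(flat)$supported))

  # a significant decrease is not an increase
  down <- mkmat(ref = c(7L, 8L, 7L, 8L, 7L, 8L, 7L, 8L), test = rep(4L, 8))
  hypd <- suppressWarnings(testHypotheses(down))
  expect_false(hypd$supported[hypd$hypothesis == "H1_DAM"])
  expect_lt(hypd$t[hypd$hypothesis == "H1_DAM"], 0)
})

test_that("count matrices round-trip and reject invalid input", {
  mat <- readCountMatrix(system.file("extdata", "synthetic_s1_counts.tsv",
                                     package = "ploidyOrigin"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(mat, f)
  back <- readCountMatrix(f)
  expect_equal(back@counts, mat@counts)
  expect_equal(loci(back), loci(mat))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tgroup\tparent\tcount", "L1\ta\tDAM\t-1"), bad)
  expect_error(readCountMatrix(bad), "non-negative")
  writeLines("locus\tgroup\tparent\tcount", bad)
  expect_error(readCountMatrix(bad), "empty")
})

test_that("calibration pins r to the boundary for boundary folds", {
  cfg <- CrossConfig(seed = 161)
  grid <- c(0, 0.5, 1)
  low <- calibrateR(1.0, cfg, grid = grid, nOffspring = 60)
  expect_lte(low$r, 0.5)
  hi <- calibrateR(2.0, cfg, grid = grid, nOffspring = 60)
  expect_true(hi$boundary || hi$r == 1)
  expect_equal(hi$r, 1)
  # the simulated curve is returned alongside
  expect_equal(hi$curve$r, grid)
})
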