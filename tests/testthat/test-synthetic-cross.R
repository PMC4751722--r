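test_that("parental genomes draw every homolog from the locus pool", {
  pools <- defaultAllelePools(8, 20)
  g <- simulateParent(6, names(pools), pools, seed = 11)
  expect_equal(g@ploidy, 6L)
  cp <- g@copies
  expect_true(all(table(cp$locus) == 6L))
  for (l in names(pools))
    expect_true(all(cp$allele[cp$locus == l] %in% pools[[l]]))

  # single-allele pool forces identical copies
  mono <- simulateParent(4, "L1", list(L1 = 150L), seed = 1)
  expect_equal(unique(mono@copies$allele), 150L)

  # seed reproducibility
  expect_equal(simulateParent(6, names(pools), pools, seed = 11)@copies,
               g@copies)

  expect_error(simulateParent(4, "L1", list(L1 = integer(0))), "pool")
})

test_that("male gametes are uniform halves of the homolog set", {
  sire6 <- TrueGenomeFixture(6L, alleles = 201:206, origin = "SIRE")
  gam <- formMaleGamete(sire6)
  expect_equal(gam@ploidy, 3L)
  expect_equal(nrow(gam@copies), 3L)

  sire2 <- TrueGenomeFixture(2L, alleles = 201:202, origin = "SIRE")
  expect_equal(formMaleGamete(sire2)@ploidy, 1L)

  odd <- TrueGenomeFixture(3L, alleles = 201:203, origin = "SIRE")
  expect_error(formMaleGamete(odd), "odd ploidy")

  # each homolog (identified by its unique allele) appears in ~50% of
  # gametes; binomial tolerance 3 s.e.
  set.seed(21)
  n <- 10000
  hits <- matrix(FALSE, n, 6)
  for (i in seq_len(n))
    hits[i, ] <- 201:206 %in% formMaleGamete(sire6)@copies$allele
  freq <- colMeans(hits)
  tol <- 3 * sqrt(0.25 / n)
  expect_true(all(abs(freq - 0.5) < tol))
})

test_that("female gamete models produce their defining genotype signatures", {
  dam <- fourAlleleDam()

  # clonal oocyte: allele multiset identical to the dam, at every locus
  set.seed(31)
  clone <- formFemaleGamete(dam, "APOMIXIS_CLONE")
  expect_equal(clone@ploidy, 4L)
  expect_equal(sort(clone@copies$allele), sort(dam@copies$allele))

  # r = 0: pure restitution, every allele duplicated, <= 2 distinct
  for (i in 1:25) {
    g <- formFemaleGamete(dam, "PB2_RETENTION", r = 0)
    counts <- table(g@copies$allele)
    expect_true(all(counts %% 2 == 0))
    expect_lte(length(counts), 2L)
  }

  # NORMAL: half the set
  expect_equal(formFemaleGamete(dam, "NORMAL")@ploidy, 2L)

  expect_error(formFemaleGamete(dam, "PB2_RETENTION", r = 1.5), "r must")
})

test_that("PB2 distinct-allele counts match the enumeration oracle mean", {
  dam <- fourAlleleDam()
  set.seed(41)
  n <- 4000
  for (r in c(0.3, 1)) {
    k <- vapply(seq_len(n), function(i)
      length(unique(formFemaleGamete(dam, "PB2_RETENTION", r)@copies$allele)),
      numeric(1))
    oracle <- pb2DistinctOracle(r)
    expMean <- sum(as.numeric(names(oracle)) * oracle)
    se <- sd(k) / sqrt(n)
    expect_lt(abs(mean(k) - expMean), 3 * se + 1e-12)
  }
})

test_that("fertilization concatenates gametes and conserves tagged copies", {
  dam <- fourAlleleDam()
  sire <- TrueGenomeFixture(6L, alleles = 201:206, origin = "SIRE")
  set.seed(51)

  oo2 <- formFemaleGamete(dam, "NORMAL")
  sp3 <- formMaleGamete(sire)
  expect_equal(fertilize(oo2, sp3)@ploidy, 5L)                 # 2n + 3n
  oo4 <- formFemaleGamete(dam, "PB2_RETENTION", r = 0.8)
  expect_equal(fertilize(oo4, formMaleGamete(sire))@ploidy, 7L) # 4n + 3n
  z8 <- fertilize(formFemaleGamete(dam, "NORMAL"),
                  list(formMaleGamete(sire), formMaleGamete(sire)))
  expect_equal(z8@ploidy, 8L)                                   # 2n+3n+3n

  # copy conservation and parent-of-origin partition
  expect_equal(nrow(z8@copies), 8L)
  expect_equal(sum(z8@copies$origin == "DAM"), 2L)
  expect_equal(sum(z8@copies$origin == "SIRE"), 6L)

  other <- TrueGenomeFixture(2L, alleles = c(1L, 2L), locus = "LX")
  expect_error(fertilize(oo2, formMaleGamete(other)), "same loci")
})

test_that("observation collapses copies to distinct sets; dropout is binomial", {
  g <- TrueGenomeFixture(4L, alleles = c(180L, 180L, 184L, 184L))
  expect_equal(observeGenotype(g, 0), list(L1 = c(180L, 184L)))

  # dropout 0 is the identity on distinct sets
  dam <- fourAlleleDam()
  expect_equal(observeGenotype(dam, 0), list(L1 = 101:104))

  set.seed(61)
  n <- 5000
  sizes <- vapply(seq_len(n), function(i)
    length(unlist(observeGenotype(dam, 0.1))), numeric(1))
  # each of 4 distinct alleles kept with prob 0.9
  se <- sqrt(4 * 0.9 * 0.1 / n)
  expect_lt(abs(mean(sizes) - 3.6), 3 * se)

  expect_error(observeGenotype(dam, 1), "dropout")
})

test_that("simulated crosses carry correct truth labels and reproduce", {
  simN <- simulateCross(CrossConfig(femaleModel = "NORMAL", seed = 71))
  expect_true(all(simN$labels$true_ploidy == 5L))
  simP <- simulateCross(CrossConfig(femaleModel = "PB2_RETENTION", seed = 71))
  expect_true(all(simP$labels$true_ploidy == 7L))
  simD <- simulateCross(CrossConfig(nSperm = 2, seed = 71))
  expect_true(all(simD$labels$true_ploidy == 8L))
  expect_true(all(simD$labels$true_mechanism == "DISPERMY"))

  again <- simulateCross(CrossConfig(femaleModel = "PB2_RETENTION", seed = 71))
  expect_equal(genotypes(again$table), genotypes(simP$table))

  # mixed design shares parents between cohorts
  mix <- simulateMixedCross(CrossConfig(femaleModel = "PB2_RETENTION",
                                        seed = 72), 3, 4)
  expect_equal(sum(mix$labels$true_ploidy == 5L), 3L)
  expect_equal(sum(mix$labels$true_ploidy == 7L), 4L)
  expect_setequal(unlist(mix$groups), mix$labels$sample)
})

test_that("clonal offspring restricted to maternal copies equal the dam", {
  sim <- simulateCross(CrossConfig(femaleModel = "APOMIXIS_CLONE",
                                   nOffspring = 5, seed = 81))
  damSets <- observeGenotype(sim$damGenome, 0)
  for (id in sim$labels$sample) {
    for (l in loci(sim$table)) {
      obs <- alleleSet(sim$table, id, l)
      expect_true(all(damSets[[l]] %in% obs))
    }
  }
})

test_that("DNA-content simulation matches its location/scale model", {
  expect_equal(simulateDnaContent(5, 1.796, cv = 0, nNuclei = 10),
               rep(5 * 1.796, 10))
  set.seed(91)
  x7 <- mean(simulateDnaContent(7, 1.8, 0.02, 3000))
  x5 <- mean(simulateDnaContent(5, 1.8, 0.02, 3000))
  seRatio <- 1.4 * 0.02 * sqrt(2 / 3000)
  expect_lt(abs(x7 / x5 - 1.4), 3 * seRatio)
  se <- 5 * 1.8 * 0.02 / sqrt(3000)
  expect_lt(abs(x5 - 9.0), 3 * se)
})
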