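test_that("ploidy excess identifies the candidate gamete contributions", {
  e0 <- ploidyExcess(5, 4, 6)
  expect_equal(e0@expectedNormal, 5L)
  expect_equal(e0@excess, 0L)
  expect_equal(ploidyExcess(7, 4, 6)@excess, 2L)  # dam gamete ploidy
  expect_equal(ploidyExcess(8, 4, 6)@excess, 3L)  # sire gamete ploidy
  expect_error(ploidyExcess(7, 3, 6), "even")
})

test_that("maternal identity fraction is the dam-coverage rate over loci", {
  sim <- simulateCross(CrossConfig(femaleModel = "APOMIXIS_CLONE",
                                   nOffspring = 3, seed = 171))
  for (id in offspringIds(sim$table))
    expect_equal(maternalIdentityFraction(sim$table, id), 1)

  # remove one dam-private allele from one offspring at one locus
  tab <- sim$table
  dam <- damId(tab); sire <- sireId(tab)
  g <- genotypes(tab)
  victim <- NULL
  for (l in loci(tab)) {
    dp <- setdiff(alleleSet(tab, dam, l), alleleSet(tab, sire, l))
    if (length(dp)) { victim <- c(l, dp[1]); break }
  }
  drop <- g$sample_id == "off_001" & g$locus == victim[1] &
    g$allele == as.integer(victim[2])
  tab2 <- GenotypeTable(sampleInfo(tab), g[!drop, ])
  expect_equal(maternalIdentityFraction(tab2, "off_001"),
               (length(loci(tab)) - 1) / length(loci(tab)))
})

test_that("the exclusion sequence maps evidence to verdicts", {
  hypYes <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                       supported = c(TRUE, FALSE, FALSE))
  hypNo <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                      supported = c(FALSE, FALSE, FALSE))

  # excess 0 is NORMAL regardless of any other input
  v <- inferMechanism(ploidyExcess(5, 4, 6), identityFraction = 1,
                      hyp = hypYes)
  expect_equal(v@verdict, "NORMAL")

  # excess = sire gamete ploidy: polyspermy
  expect_equal(inferMechanism(ploidyExcess(8, 4, 6), 0.5)@verdict,
               "POLYSPERMY")

  # excess = dam gamete ploidy: clone when fully identical to the dam
  expect_equal(inferMechanism(ploidyExcess(7, 4, 6), 1, hypYes)@verdict,
               "MATERNAL_CLONE_APOMIXIS_OR_ENDOMITOSIS")
  # ... PB2 retention when recombination broke identity and H1 holds
  expect_equal(inferMechanism(ploidyExcess(7, 4, 6), 6 / 8, hypYes)@verdict,
               "MATERNAL_SDM_PB2")
  # ... unresolved without the dam-private increase
  expect_equal(inferMechanism(ploidyExcess(7, 4, 6), 6 / 8, hypNo)@verdict,
               "UNRESOLVED")

  # an excess matching no gamete ploidy stays unresolved
  expect_equal(inferMechanism(ploidyExcess(6, 4, 6), 1, hypYes)@verdict,
               "UNRESOLVED")

  # every verdict carries an evidence trail
  expect_gte(nrow(inferMechanism(ploidyExcess(7, 4, 6), 1)@evidence), 2L)
})

test_that("polyspermy is never inferred when the arithmetic excludes it", {
  hyp <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                    supported = c(FALSE, TRUE, FALSE))
  for (obs in 2:12) {
    e <- ploidyExcess(obs, 4, 6)
    v <- inferMechanism(e, identityFraction = 0.5, hyp = hyp)
    if (v@verdict == "POLYSPERMY") expect_equal(e@excess, 3L)
  }
})

test_that("equal parental gamete ploidies fall back to genotype evidence", {
  h1 <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                   supported = c(TRUE, FALSE, FALSE))
  h2 <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                   supported = c(FALSE, TRUE, FALSE))
  both <- data.frame(hypothesis = c("H1_DAM", "H2_SIRE", "H3_BOTH"),
                     supported = c(TRUE, TRUE, TRUE))
  e <- ploidyExcess(6, 4, 4)  # excess 2 = both gamete ploidies
  expect_equal(inferMechanism(e, 0.5, h1)@verdict, "MATERNAL_SDM_PB2")
  expect_equal(inferMechanism(e, 0.5, h2)@verdict, "POLYSPERMY")
  expect_equal(inferMechanism(e, 0.5, both)@verdict, "UNRESOLVED")
  expect_equal(inferMechanism(e, 0.5, NULL)@verdict, "UNRESOLVED")
})

test_that("dropout-tolerant identity threshold follows the dropout model", {
  expect_equal(dropoutIdentityThreshold(8, 0), 1)
  expect_equal(dropoutIdentityThreshold(8, 0.02), 7 / 8)
  expect_lte(dropoutIdentityThreshold(8, 0.2), 6 / 8)
})

test_that("cross classification runs the full chain deterministically", {
  cls <- classifySimulatedCross("PB2_RETENTION", 1, seed = 181, dropout = 0)
  expect_equal(cls$summary$cross_verdict, "MATERNAL_SDM_PB2")
  expect_equal(unname(cls$summary$anomalous["7"]), 7L)
  expect_equal(cls$summary$n_normal, 7L)
  anom <- cls$verdicts[cls$verdicts$called_ploidy == 7, ]
  expect_true(all(anom$verdict == "MATERNAL_SDM_PB2"))
  expect_true(all(anom$identity_fraction < 1))

  # identical inputs give identical verdicts
  cls2 <- classifySimulatedCross("PB2_RETENTION", 1, seed = 181, dropout = 0)
  expect_identical(cls$verdicts, cls2$verdicts)

  # clonal cross at dropout 0: exact identity, clone verdicts
  clsA <- classifySimulatedCross("APOMIXIS_CLONE", 1, seed = 182,
                                 dropout = 0)
  anomA <- clsA$verdicts[clsA$verdicts$called_ploidy == 7, ]
  expect_true(all(anomA$identity_fraction == 1))
  expect_true(all(anomA$verdict ==
                    "MATERNAL_CLONE_APOMIXIS_OR_ENDOMITOSIS"))

  # all-euploid cross: nothing to explain
  clsN <- classifySimulatedCross("NORMAL", 1, seed = 183, dropout = 0)
  expect_equal(clsN$summary$message, "no spontaneous polyploids detected")
  expect_equal(clsN$summary$cross_verdict, "NORMAL")
})
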