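# Shared fixtures and independent oracles, built in code.

# Quiet wrapper: private-allele counting chatters about excluded loci.
cpa <- function(...) suppressMessages(countPrivateAlleles(...))

# Two-parent, two-offspring toy cross used across the IO and counting
# tests. Locus L1: dam-private 180, sire-private 196, shared 184.
# Locus L2: fully informative (disjoint parents).
# Locus L3: uninformative (parents identical).
toyCrossTable <- function() {
  g <- rbind(
    data.frame(sample_id = "dam", locus = "L1", allele = c(180L, 184L)),
    data.frame(sample_id = "dam", locus = "L2", allele = c(300L, 304L)),
    data.frame(sample_id = "dam", locus = "L3", allele = 500L),
    data.frame(sample_id = "sire", locus = "L1", allele = c(184L, 196L)),
    data.frame(sample_id = "sire", locus = "L2", allele = c(320L, 324L)),
    data.frame(sample_id = "sire", locus = "L3", allele = 500L),
    data.frame(sample_id = "kid1", locus = "L1", allele = c(180L, 184L)),
    data.frame(sample_id = "kid1", locus = "L2", allele = c(300L, 320L)),
    data.frame(sample_id = "kid1", locus = "L3", allele = 500L),
    data.frame(sample_id = "kid2", locus = "L1", allele = c(184L, 196L)),
    data.frame(sample_id = "kid2", locus = "L2", allele = c(304L, 324L)),
    data.frame(sample_id = "kid2", locus = "L3", allele = 500L))
  GenotypeTable(
    samples = data.frame(sample_id = c("dam", "sire", "kid1", "kid2"),
                         role = c("DAM", "SIRE", "OFFSPRING", "OFFSPRING"),
                         ploidy_label = c(4L, 6L, NA, NA)),
    genotypes = g)
}

# A tetraploid dam with four distinct alleles at a single locus; the
# homolog -> allele map is a bijection, so gamete alleles identify the
# homologs they came from.
fourAlleleDam <- function() {
  TrueGenomeFixture(4L, alleles = c(101L, 102L, 103L, 104L))
}

TrueGenomeFixture <- function(ploidy, alleles, locus = "L1",
                              origin = "DAM") {
  stopifnot(length(alleles) == ploidy)
  new("TrueGenome", ploidy = ploidy,
      copies = data.frame(locus = locus, homolog = seq_len(ploidy),
                          allele = as.integer(alleles), origin = origin,
                          stringsAsFactors = FALSE))
}

# Brute-force enumeration oracle for the PB2 gamete at one locus with 4
# distinct maternal alleles: enumerate all 6 homolog-half choices and,
# for each of the two duplicated copies, the 3 restoration outcomes
# (keep the sister allele with prob 1-r, or take either non-selected
# homolog's allele with prob r/2 each). Returns P(number of distinct
# maternal alleles in the gamete) for counts "2", "3", "4".
pb2DistinctOracle <- function(r) {
  halves <- utils::combn(4, 2)
  probs <- c(1 - r, r / 2, r / 2)
  acc <- c("2" = 0, "3" = 0, "4" = 0)
  for (h in seq_len(ncol(halves))) {
    sel <- halves[, h]
    ns <- setdiff(1:4, sel)
    for (o1 in 1:3) {
      for (o2 in 1:3) {
        rep1 <- c(sel[1], ns)[o1]
        rep2 <- c(sel[2], ns)[o2]
        k <- length(unique(c(sel, rep1, rep2)))
        acc[as.character(k)] <- acc[as.character(k)] +
          probs[o1] * probs[o2] / ncol(halves)
      }
    }
  }
  acc
}

# End-to-end helper: cytometry measurements and ploidy calls for the
# offspring of a simulated cross, from their true ploidies.
simulateCallsFromTruth <- function(sim, perSetPg = 1.796, cv = 0.02,
                                   nNuclei = 3000,
                                   candidates = c(5L, 7L, 8L)) {
  meas <- data.frame(
    sample = sim$labels$sample,
    value = vapply(sim$labels$true_ploidy, function(p)
      mean(simulateDnaContent(p, perSetPg, cv, nNuclei)), numeric(1)),
    stringsAsFactors = FALSE)
  callPloidyBatch(meas, perSetPg, candidates)$calls
}

# One full classification run for a mixed cross under a given mechanism.
classifySimulatedCross <- function(femaleModel, nSperm, seed,
                                   dropout = 0.02, r = 0.8,
                                   identityThreshold =
                                     dropoutIdentityThreshold(8, dropout)) {
  cfg <- CrossConfig(femaleModel = femaleModel, nSperm = nSperm, r = r,
                     observationDropout = dropout, seed = seed)
  sim <- simulateMixedCross(cfg, nNormal = 7, nAnomalous = 7)
  calls <- simulateCallsFromTruth(sim)
  suppressWarnings(classifyCross(sim$table, calls,
                                 identityThreshold = identityThreshold))
}
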