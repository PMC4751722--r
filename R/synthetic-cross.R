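# Simulator of a polysomic cross with known ground truth. All functions
# draw from the session RNG; simulateCross() seeds it once from its
# config and sub-operations never reseed.

#' Default per-locus allele pools
#'
#' Builds allele pools mimicking tetranucleotide microsatellites: locus i
#' offers \code{poolSize} fragment lengths starting at 100 + 60(i-1) bp
#' in 4 bp steps. Pool size controls parental heterozygosity and the
#' expected number of private alleles per parent.
#'
#' @param nLoci number of loci.
#' @param poolSize number of distinct allele lengths per locus.
#' @return Named list (locus label -> integer vector of lengths).
#' @export
defaultAllelePools <- function(nLoci, poolSize) {
  pools <- lapply(seq_len(nLoci), function(i)
    as.integer(100 + 60 * (i - 1) + 4 * (0:(poolSize - 1))))
  names(pools) <- sprintf("L%02d", seq_len(nLoci))
  pools
}

#' Simulate a parental genome
#'
#' Each of the \code{ploidy} homologs at each locus draws one allele
#' uniformly from that locus's pool.
#'
#' @param ploidy functional ploidy (number of allele copies per locus).
#' @param loci character vector of locus labels.
#' @param allelePool named list mapping each locus to its allele pool.
#' @param origin parent-of-origin tag stamped on every copy.
#' @param seed optional integer; when given the RNG is seeded first so
#'   the genome is reproducible in isolation.
#' @return A \code{\linkS4class{TrueGenome}}.
#' @export
simulateParent <- function(ploidy, loci, allelePool, origin = "PARENT",
                           seed = NULL) {
  ploidy <- as.integer(ploidy)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!all(loci %in% names(allelePool)))
    stop("allelePool must cover every locus")
  if (any(lengths(allelePool[loci]) < 1L))
    stop("every locus needs a pool of at least one allele")
  copies <- do.call(rbind, lapply(loci, function(l) {
    pool <- allelePool[[l]]
    data.frame(locus = l, homolog = seq_len(ploidy),
               allele = pool[sample.int(length(pool), ploidy, replace = TRUE)],
               origin = origin, stringsAsFactors = FALSE)
  }))
  TrueGenome(ploidy, copies)
}

# Uniform random half of the homolog set, independently per locus
# (polysomic inheritance at unlinked loci: random bivalent pairing,
# no preferential pairing, no double reduction).
.reduceHalf <- function(genome) {
  k <- genome@ploidy %/% 2L
  cp <- genome@copies
  picked <- lapply(split(cp, cp$locus), function(d) {
    d[sample.int(nrow(d), k), , drop = FALSE]
  })
  do.call(rbind, picked)
}

.asGamete <- function(copyRows, nSets, origin) {
  copyRows$origin <- origin
  # renumber homologs 1..nSets within each locus
  copyRows <- copyRows[order(copyRows$locus), , drop = FALSE]
  copyRows$homolog <- unlist(lapply(split(seq_len(nrow(copyRows)),
                                          copyRows$locus),
                                    function(ix) seq_along(ix)),
                             use.names = FALSE)
  TrueGenome(nSets, copyRows)
}

#' Form a reduced male gamete
#'
#' A spermatozoon carries a uniformly random half of the sire's homolog
#' set at every locus (e.g. triploid sperm from a hexaploid sire).
#'
#' @param sire \code{\linkS4class{TrueGenome}} of even ploidy.
#' @param origin parent-of-origin tag for the gamete's copies.
#' @return A \code{TrueGenome} of ploidy \code{ploidy(sire)/2}.
#' @export
formMaleGamete <- function(sire, origin = "SIRE") {
  if (sire@ploidy %% 2L != 0L)
    stop("cannot form a reduced gamete from odd ploidy ", sire@ploidy)
  .asGamete(.reduceHalf(sire), sire@ploidy %/% 2L, origin)
}

#' Form a female gamete under a given oocyte model
#'
#' \code{NORMAL}: a reduced oocyte, a uniformly random half of the dam's
#' homologs per locus. \code{PB2_RETENTION}: an unreduced oocyte built by
#' second-division restitution — a reduced set is formed, every copy is
#' duplicated, and independently per duplicated copy with probability
#' \code{r} the duplicate's allele is replaced by the allele of a
#' uniformly chosen non-selected homolog (heterozygosity restored by a
#' centromere-to-locus crossover); with probability \code{1 - r} the
#' sister copy is kept (restitution homozygosity).
#' \code{APOMIXIS_CLONE}: an unreduced clonal oocyte, an exact copy of
#' the dam's full copy list (covers apomixis and premeiotic endomitosis).
#'
#' @param dam \code{\linkS4class{TrueGenome}} of even ploidy.
#' @param model one of \code{gameteModels()}.
#' @param r per-locus heterozygosity-restoration probability in \[0, 1\];
#'   only used by \code{PB2_RETENTION}.
#' @param origin parent-of-origin tag for the gamete's copies.
#' @return A \code{TrueGenome}: ploidy \code{ploidy(dam)/2} for NORMAL,
#'   \code{ploidy(dam)} otherwise.
#' @export
formFemaleGamete <- function(dam, model = gameteModels(), r = 0.8,
                             origin = "DAM") {
  model <- match.arg(model)
  if (dam@ploidy %% 2L != 0L)
    stop("cannot form a gamete from odd ploidy ", dam@ploidy)
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (model == "APOMIXIS_CLONE")
    return(.asGamete(dam@copies, dam@ploidy, origin))
  k <- dam@ploidy %/% 2L
  if (model == "NORMAL")
    return(.asGamete(.reduceHalf(dam), k, origin))
  # PB2_RETENTION
  cp <- dam@copies
  out <- lapply(split(cp, cp$locus), function(d) {
    sel <- sample.int(nrow(d), k)
    nonsel <- setdiff(seq_len(nrow(d)), sel)
    kept <- d[sel, , drop = FALSE]
    dup <- kept
    restore <- stats::runif(k) < r
    if (any(restore))
      dup$allele[restore] <- d$allele[nonsel[sample.int(length(nonsel),
                                                        sum(restore),
                                                        replace = TRUE)]]
    rbind(kept, dup)
  })
  .asGamete(do.call(rbind, out), dam@ploidy, origin)
}

#' Fuse gametes into a zygote
#'
#' Concatenates the copy lists of one oocyte and one or two spermatozoa;
#' functional ploidy is the sum of the gamete set counts and
#' parent-of-origin tags are preserved, so the zygote's copies partition
#' exactly into the contributing gametes.
#'
#' @param oocyte a \code{\linkS4class{TrueGenome}} gamete.
#' @param sperm a single gamete or a list of 1 or 2 gametes (dispermy).
#' @return A \code{TrueGenome} zygote.
#' @export
fertilize <- function(oocyte, sperm) {
  if (is(sperm, "TrueGenome")) sperm <- list(sperm)
  if (!length(sperm) %in% 1:2)
    stop("fertilization requires 1 (monospermic) or 2 (dispermic) sperm")
  gametes <- c(list(oocyte), sperm)
  lociSets <- lapply(gametes, function(g) sort(unique(g@copies$locus)))
  if (!all(vapply(lociSets[-1], identical, logical(1), lociSets[[1]])))
    stop("all gametes must cover the same loci")
  copies <- do.call(rbind, lapply(gametes, slot, "copies"))
  total <- sum(vapply(gametes, slot, integer(1), "ploidy"))
  copies <- copies[order(copies$locus), , drop = FALSE]
  copies$homolog <- unlist(lapply(split(seq_len(nrow(copies)), copies$locus),
                                  seq_along), use.names = FALSE)
  TrueGenome(total, copies)
}

#' Observe a genome as a presence-only genotype
#'
#' Collapses allele copies to the set of distinct lengths per locus (the
#' microsatellite allele phenotype) and drops each distinct allele
#' independently with probability \code{dropout}; a locus losing every
#' allele becomes a missing genotype (absent from the result).
#'
#' @param genome a \code{\linkS4class{TrueGenome}}.
#' @param dropout per-allele dropout probability in \[0, 1).
#' @return Named list (locus -> sorted integer vector of allele lengths).
#' @export
observeGenotype <- function(genome, dropout = 0) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  sets <- lapply(split(genome@copies$allele, genome@copies$locus),
                 function(a) sort(unique(a)))
  if (dropout > 0)
    sets <- lapply(sets, function(a) a[stats::runif(length(a)) >= dropout])
  sets[lengths(sets) > 0L]
}

#' Simulate a full cross with ground-truth labels
#'
#' Generates (or reuses) the parental genomes, forms gametes under the
#' configured female model and sperm count, fuses zygotes, applies
#' presence-only observation with dropout to parents and offspring
#' alike, and returns the genotype table together with per-offspring
#' truth labels. Fully reproducible: the RNG is seeded once from
#' \code{config@seed}.
#'
#' @param config a \code{\linkS4class{CrossConfig}}.
#' @param damGenome,sireGenome optional pre-built parental
#'   \code{TrueGenome}s; when supplied they are used as-is, which allows
#'   several mechanism arms to share the same parents.
#' @param allelePools optional named list of per-locus allele pools;
#'   defaults to \code{defaultAllelePools(config@nLoci,
#'   config@allelePoolSize)}.
#' @return A list with elements \code{table}
#'   (\code{\linkS4class{GenotypeTable}}), \code{labels} (data.frame
#'   \code{sample}, \code{true_mechanism}, \code{true_ploidy}),
#'   \code{damGenome}, \code{sireGenome}, and \code{config}.
#' @export
#' @examples
#' sim <- simulateCross(CrossConfig(femaleModel = "PB2_RETENTION",
#'                                  nOffspring = 7, seed = 42))
#' sim$labels$true_ploidy  # all 7n: 4n oocyte + 3n spermatozoon
simulateCross <- function(config, damGenome = NULL, sireGenome = NULL,
                          allelePools = NULL) {
  stopifnot(is(config, "CrossConfig"))
  validObject(config)
  set.seed(config@seed)
  if (is.null(allelePools))
    allelePools <- defaultAllelePools(config@nLoci, config@allelePoolSize)
  lc <- names(allelePools)
  if (is.null(damGenome))
    damGenome <- simulateParent(config@damPloidy, lc, allelePools,
                                origin = "DAM")
  if (is.null(sireGenome))
    sireGenome <- simulateParent(config@sirePloidy, lc, allelePools,
                                 origin = "SIRE")
  mech <- if (config@nSperm == 2L) "DISPERMY" else config@femaleModel
  oocyteSets <- if (config@femaleModel == "NORMAL") config@damPloidy %/% 2L
                else config@damPloidy
  truePloidy <- oocyteSets + config@nSperm * (config@sirePloidy %/% 2L)

  gRows <- list()
  addObs <- function(id, sets) {
    if (!length(sets)) return()
    gRows[[length(gRows) + 1L]] <<- data.frame(
      sample_id = id, locus = rep(names(sets), lengths(sets)),
      allele = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE)
  }
  addObs("dam", observeGenotype(damGenome, config@observationDropout))
  addObs("sire", observeGenotype(sireGenome, config@observationDropout))

  offIds <- sprintf("off_%03d", seq_len(config@nOffspring))
  for (id in offIds) {
    oocyte <- formFemaleGamete(damGenome, config@femaleModel, config@r)
    sperm <- replicate(config@nSperm, formMaleGamete(sireGenome),
                       simplify = FALSE)
    zygote <- fertilize(oocyte, sperm)
    addObs(id, observeGenotype(zygote, config@observationDropout))
  }
  samples <- data.frame(
    sample_id = c("dam", "sire", offIds),
    role = c("DAM", "SIRE", rep("OFFSPRING", length(offIds))),
    ploidy_label = c(config@damPloidy, config@sirePloidy,
                     rep(truePloidy, length(offIds))),
    stringsAsFactors = FALSE)
  table <- GenotypeTable(samples, do.call(rbind, gRows))
  labels <- data.frame(sample = offIds,
                       true_mechanism = rep(mech, length(offIds)),
                       true_ploidy = rep(truePloidy, length(offIds)),
                       stringsAsFactors = FALSE)
  list(table = table, labels = labels, damGenome = damGenome,
       sireGenome = sireGenome, config = config)
}

#' Simulate a cross with a normal and an anomalous sibling cohort
#'
#' Mirrors the study design in which a minority of spontaneously
#' polyploid offspring co-occur with euploid full siblings: both cohorts
#' descend from the same simulated parents, the normal cohort from
#' reduced oocytes and monospermic fertilization, the anomalous cohort
#' from the configured \code{femaleModel}/\code{nSperm}. One RNG stream,
#' seeded once from \code{config@seed}.
#'
#' @param config a \code{\linkS4class{CrossConfig}}; its
#'   \code{femaleModel} and \code{nSperm} describe the anomalous arm.
#' @param nNormal,nAnomalous cohort sizes (default 7 and 7, the analyzed
#'   group sizes of the study design).
#' @return As \code{\link{simulateCross}}, plus a \code{groups} element
#'   (list with members \code{normal} and \code{anomalous}) ready for
#'   \code{\link{countPrivateAlleles}}.
#' @export
simulateMixedCross <- function(config, nNormal = 7, nAnomalous = 7) {
  stopifnot(is(config, "CrossConfig"))
  validObject(config)
  set.seed(config@seed)
  pools <- defaultAllelePools(config@nLoci, config@allelePoolSize)
  lc <- names(pools)
  damGenome <- simulateParent(config@damPloidy, lc, pools, origin = "DAM")
  sireGenome <- simulateParent(config@sirePloidy, lc, pools, origin = "SIRE")
  normPloidy <- (config@damPloidy + config@sirePloidy) %/% 2L
  anomOocyte <- if (config@femaleModel == "NORMAL") config@damPloidy %/% 2L
                else config@damPloidy
  anomPloidy <- anomOocyte + config@nSperm * (config@sirePloidy %/% 2L)
  mech <- if (config@nSperm == 2L) "DISPERMY" else config@femaleModel

  gRows <- list()
  addObs <- function(id, sets) {
    if (!length(sets)) return()
    gRows[[length(gRows) + 1L]] <<- data.frame(
      sample_id = id, locus = rep(names(sets), lengths(sets)),
      allele = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE)
  }
  addObs("dam", observeGenotype(damGenome, config@observationDropout))
  addObs("sire", observeGenotype(sireGenome, config@observationDropout))
  normIds <- sprintf("n_%03d", seq_len(nNormal))
  anomIds <- sprintf("a_%03d", seq_len(nAnomalous))
  for (id in normIds) {
    zyg <- fertilize(formFemaleGamete(damGenome, "NORMAL"),
                     formMaleGamete(sireGenome))
    addObs(id, observeGenotype(zyg, config@observationDropout))
  }
  for (id in anomIds) {
    oocyte <- formFemaleGamete(damGenome, config@femaleModel, config@r)
    sperm <- replicate(config@nSperm, formMaleGamete(sireGenome),
                       simplify = FALSE)
    addObs(id, observeGenotype(fertilize(oocyte, sperm),
                               config@observationDropout))
  }
  samples <- data.frame(
    sample_id = c("dam", "sire", normIds, anomIds),
    role = c("DAM", "SIRE", rep("OFFSPRING", nNormal + nAnomalous)),
    ploidy_label = c(config@damPloidy, config@sirePloidy,
                     rep(normPloidy, nNormal), rep(anomPloidy, nAnomalous)),
    stringsAsFactors = FALSE)
  table <- GenotypeTable(samples, do.call(rbind, gRows))
  labels <- data.frame(
    sample = c(normIds, anomIds),
    true_mechanism = c(rep("NORMAL", nNormal), rep(mech, nAnomalous)),
    true_ploidy = c(rep(normPloidy, nNormal), rep(anomPloidy, nAnomalous)),
    stringsAsFactors = FALSE)
  list(table = table, labels = labels, damGenome = damGenome,
       sireGenome = sireGenome, config = config,
       groups = list(normal = normIds, anomalous = anomIds))
}

#' Simulate per-nucleus DNA-content measurements
#'
#' Draws \code{nNuclei} fluorescence-equivalent pg values around
#' \code{ploidy * perSetPg} with Gaussian noise of relative spread
#' \code{cv}, emulating an erythrocyte peak on a flow cytometer; a
#' specimen's measurement is conventionally the mean over at least 3000
#' nuclei.
#'
#' @param ploidy functional ploidy of the specimen.
#' @param perSetPg DNA content of one functional haploid set, pg.
#' @param cv coefficient of variation of the per-nucleus values.
#' @param nNuclei number of nuclei measured.
#' @return Numeric vector of per-nucleus pg values.
#' @export
simulateDnaContent <- function(ploidy, perSetPg, cv = 0.02, nNuclei = 3000) {
  if (perSetPg <= 0) stop("perSetPg must be positive")
  if (cv < 0) stop("cv must be non-negative")
  if (nNuclei < 1) stop("nNuclei must be >= 1")
  mu <- ploidy * perSetPg
  rnorm(nNuclei, mean = mu, sd = cv * mu)
}
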