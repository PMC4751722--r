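#' @import methods
#' @importFrom stats pt sd rnorm shapiro.test setNames
#' @importFrom utils read.delim write.table
NULL

.GAMETE_MODELS <- c("NORMAL", "PB2_RETENTION", "APOMIXIS_CLONE")
.ROLES <- c("DAM", "SIRE", "OFFSPRING")
.VERDICTS <- c("NORMAL", "MATERNAL_SDM_PB2",
               "MATERNAL_CLONE_APOMIXIS_OR_ENDOMITOSIS",
               "POLYSPERMY", "UNRESOLVED")

#' Female gamete formation models
#'
#' The three oocyte formation models the simulator and the mechanism
#' classifier distinguish: \code{"NORMAL"} (reduced oocyte, half the
#' maternal homolog set), \code{"PB2_RETENTION"} (unreduced oocyte by
#' retention of the second polar body in meiosis II, i.e. second-division
#' restitution: sister sets kept, heterozygosity restored distal to
#' crossovers), and \code{"APOMIXIS_CLONE"} (unreduced clonal oocyte,
#' genetically identical to the dam; covers both apomixis and premeiotic
#' endomitosis, which produce the same genotype signature).
#'
#' @return Character vector of the model names.
#' @export
#' @examples
#' gameteModels()
gameteModels <- function() .GAMETE_MODELS

#' Configuration of a simulated polysomic cross
#'
#' Holds every parameter of the synthetic cross generator. Defaults
#' describe the study cross the package targets: a functional tetraploid
#' (4n) dam crossed with a functional hexaploid (6n) sire, genotyped at 8
#' polymorphic microsatellite loci, with presence-only allele scoring.
#'
#' @slot damPloidy integer, functional ploidy of the dam (even, >= 2).
#' @slot sirePloidy integer, functional ploidy of the sire (even, >= 2).
#' @slot nLoci integer, number of unlinked microsatellite loci.
#' @slot allelePoolSize integer, number of distinct allele lengths
#'   available per locus; parents draw homolog alleles uniformly from
#'   this pool, so parental heterozygosity and allele sharing emerge from
#'   the pool size.
#' @slot r numeric in \[0, 1\], per-locus heterozygosity-restoration
#'   probability of the PB2-retention gamete model. It subsumes the
#'   centromere-to-locus recombination distance: with probability
#'   \code{r} a duplicated allele copy is replaced by the allele of a
#'   non-selected homolog (crossover-restored heterozygosity), with
#'   probability \code{1 - r} the sister copy is kept (restitution
#'   homozygosity).
#' @slot femaleModel one of \code{gameteModels()}.
#' @slot nSperm integer 1 (monospermic) or 2 (dispermic fertilization).
#' @slot nOffspring integer, number of offspring to simulate.
#' @slot observationDropout numeric in \[0, 1), probability that a
#'   distinct allele present in the genome is missed by genotyping.
#' @slot seed integer seed; all randomness of \code{\link{simulateCross}}
#'   flows from one generator seeded with it.
#' @export
setClass("CrossConfig",
  representation(
    damPloidy = "integer", sirePloidy = "integer",
    nLoci = "integer", allelePoolSize = "integer",
    r = "numeric", femaleModel = "character",
    nSperm = "integer", nOffspring = "integer",
    observationDropout = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@damPloidy < 2L || object@damPloidy %% 2L != 0L)
      msg <- c(msg, "damPloidy must be an even integer >= 2")
    if (object@sirePloidy < 2L || object@sirePloidy %% 2L != 0L)
      msg <- c(msg, "sirePloidy must be an even integer >= 2")
    if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
    if (object@allelePoolSize < 1L)
      msg <- c(msg, "allelePoolSize must be >= 1")
    if (object@r < 0 || object@r > 1) msg <- c(msg, "r must be in [0, 1]")
    if (!object@femaleModel %in% .GAMETE_MODELS)
      msg <- c(msg, paste("femaleModel must be one of:",
                          paste(.GAMETE_MODELS, collapse = ", ")))
    if (!object@nSperm %in% c(1L, 2L)) msg <- c(msg, "nSperm must be 1 or 2")
    if (object@nOffspring < 0L) msg <- c(msg, "nOffspring must be >= 0")
    if (object@observationDropout < 0 || object@observationDropout >= 1)
      msg <- c(msg, "observationDropout must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn CrossConfig-class Constructor with the study-cross defaults.
#' @param damPloidy,sirePloidy,nLoci,allelePoolSize,r,femaleModel,nSperm,nOffspring,observationDropout,seed
#'   see the corresponding slots.
#' @return A validated \code{CrossConfig} object.
#' @export
#' @examples
#' CrossConfig(femaleModel = "PB2_RETENTION", nOffspring = 7)
CrossConfig <- function(damPloidy = 4, sirePloidy = 6, nLoci = 8,
                        allelePoolSize = 12, r = 0.8,
                        femaleModel = "NORMAL", nSperm = 1,
                        nOffspring = 7, observationDropout = 0,
                        seed = 1) {
  new("CrossConfig",
      damPloidy = as.integer(damPloidy), sirePloidy = as.integer(sirePloidy),
      nLoci = as.integer(nLoci), allelePoolSize = as.integer(allelePoolSize),
      r = as.numeric(r), femaleModel = as.character(femaleModel),
      nSperm = as.integer(nSperm), nOffspring = as.integer(nOffspring),
      observationDropout = as.numeric(observationDropout),
      seed = as.integer(seed))
}

setMethod("show", "CrossConfig", function(object) {
  cat("CrossConfig:", object@damPloidy, "n dam x ", object@sirePloidy,
      "n sire, ", object@nLoci, " loci\n", sep = "")
  cat("  female model: ", object@femaleModel,
      " (r = ", object@r, "), sperm: ", object@nSperm, "\n", sep = "")
  cat("  offspring: ", object@nOffspring,
      ", dropout: ", object@observationDropout,
      ", seed: ", object@seed, "\n", sep = "")
})

#' Fully known multilocus genome (or gamete) of a simulated individual
#'
#' Simulator-internal representation carrying every allele copy with its
#' homolog index and parent of origin, so that ground truth (dosage,
#' inheritance path) is available even though observed genotypes are
#' presence-only. Gametes use the same representation with \code{ploidy}
#' equal to the number of genome sets they carry.
#'
#' @slot ploidy integer, number of allele copies per locus.
#' @slot copies data.frame with columns \code{locus} (character),
#'   \code{homolog} (integer in 1..ploidy), \code{allele} (positive
#'   integer fragment length, bp), \code{origin} (character parent tag).
#' @export
setClass("TrueGenome",
  representation(ploidy = "integer", copies = "data.frame"),
  validity = function(object) {
    cp <- object@copies
    need <- c("locus", "homolog", "allele", "origin")
    if (!all(need %in% names(cp)))
      return(paste("copies must have columns:", paste(need, collapse = ", ")))
    if (nrow(cp)) {
      tab <- table(cp$locus)
      if (any(tab != object@ploidy))
        return("each locus must carry exactly `ploidy` allele copies")
      if (any(cp$homolog < 1L | cp$homolog > object@ploidy))
        return("homolog indices must lie in 1..ploidy")
      if (any(cp$allele <= 0L))
        return("allele lengths must be positive integers")
    }
    TRUE
  })

TrueGenome <- function(ploidy, copies) {
  copies$locus <- as.character(copies$locus)
  copies$homolog <- as.integer(copies$homolog)
  copies$allele <- as.integer(copies$allele)
  copies$origin <- as.character(copies$origin)
  rownames(copies) <- NULL
  new("TrueGenome", ploidy = as.integer(ploidy), copies = copies)
}

setMethod("show", "TrueGenome", function(object) {
  nl <- length(unique(object@copies$locus))
  cat("TrueGenome: functional ploidy ", object@ploidy, ", ",
      nl, " loci, ", nrow(object@copies), " allele copies\n", sep = "")
})

#' Table of presence-only microsatellite genotypes for one cross
#'
#' Container for the genotypes of one dam, one sire and their offspring
#' at a shared set of loci. Genotypes are allele \emph{phenotypes}: the
#' set of distinct fragment lengths observed at a locus, with no dosage,
#' which is all that polyploid microsatellite electropherograms yield.
#' A missing genotype is simply the absence of rows for that
#' (sample, locus) pair.
#'
#' @slot samples data.frame with columns \code{sample_id},
#'   \code{role} (DAM/SIRE/OFFSPRING) and \code{ploidy_label}
#'   (integer or NA), one row per individual, in display order.
#' @slot genotypes long data.frame with columns \code{sample_id},
#'   \code{locus}, \code{allele} (positive integer bp); one row per
#'   distinct observed allele.
#' @slot loci character, ordered union of loci across individuals.
#' @export
setClass("GenotypeTable",
  representation(samples = "data.frame", genotypes = "data.frame",
                 loci = "character"),
  validity = function(object) {
    msg <- character(0)
    s <- object@samples; g <- object@genotypes
    if (!all(c("sample_id", "role", "ploidy_label") %in% names(s)))
      msg <- c(msg, "samples needs columns sample_id, role, ploidy_label")
    if (!all(c("sample_id", "locus", "allele") %in% names(g)))
      msg <- c(msg, "genotypes needs columns sample_id, locus, allele")
    if (length(msg)) return(msg)
    if (anyDuplicated(s$sample_id)) msg <- c(msg, "sample_ids must be unique")
    if (!all(s$role %in% .ROLES))
      msg <- c(msg, "roles must be DAM, SIRE or OFFSPRING")
    if (sum(s$role == "DAM") != 1L) msg <- c(msg, "exactly one DAM required")
    if (sum(s$role == "SIRE") != 1L) msg <- c(msg, "exactly one SIRE required")
    if (nrow(g)) {
      if (!all(g$sample_id %in% s$sample_id))
        msg <- c(msg, "genotype rows for unknown sample_id")
      if (any(is.na(g$allele)) || any(g$allele <= 0L))
        msg <- c(msg, "allele lengths must be positive integers")
      if (anyDuplicated(g[c("sample_id", "locus", "allele")]))
        msg <- c(msg, "duplicate (sample, locus, allele) rows violate set semantics")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn GenotypeTable-class Constructor; merges duplicate allele
#'   rows (set semantics) and derives the ordered locus union.
#' @param samples,genotypes see the corresponding slots;
#'   \code{ploidy_label} may be omitted from \code{samples}.
#' @return A validated \code{GenotypeTable}.
#' @export
GenotypeTable <- function(samples, genotypes) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (is.null(samples$ploidy_label)) samples$ploidy_label <- NA_integer_
  samples$sample_id <- as.character(samples$sample_id)
  samples$role <- as.character(samples$role)
  samples$ploidy_label <- as.integer(samples$ploidy_label)
  if (nrow(genotypes)) {
    genotypes$sample_id <- as.character(genotypes$sample_id)
    genotypes$locus <- as.character(genotypes$locus)
    genotypes$allele <- as.integer(genotypes$allele)
    genotypes <- unique(genotypes[c("sample_id", "locus", "allele")])
  } else {
    genotypes <- data.frame(sample_id = character(0), locus = character(0),
                            allele = integer(0), stringsAsFactors = FALSE)
  }
  rownames(samples) <- rownames(genotypes) <- NULL
  loci <- unique(genotypes$locus)
  new("GenotypeTable", samples = samples[c("sample_id", "role", "ploidy_label")],
      genotypes = genotypes, loci = loci)
}

setMethod("show", "GenotypeTable", function(object) {
  s <- object@samples
  cat("GenotypeTable: ", nrow(s), " individuals (",
      sum(s$role == "OFFSPRING"), " offspring), ",
      length(object@loci), " loci\n", sep = "")
  cat("  dam: ", s$sample_id[s$role == "DAM"],
      "  sire: ", s$sample_id[s$role == "SIRE"], "\n", sep = "")
})

#' Per-locus private-allele count matrix
#'
#' Counts of distinct dam-private and sire-private alleles, per locus and
#' per offspring group (e.g. the pentaploid versus the heptaploid
#' full-sib group). Group counts are sums over the group's individuals of
#' each individual's count of distinct parent-private alleles observed at
#' the locus ("coded 1" per private allele).
#'
#' @slot loci ordered character vector of (informative) loci.
#' @slot groups named list mapping group label to member sample ids
#'   (may hold empty vectors when the matrix was read from a count file).
#' @slot counts data.frame with columns \code{locus}, \code{group},
#'   \code{parent} (DAM/SIRE) and \code{count} (non-negative integer).
#' @slot individualCounts data.frame with per-individual per-locus
#'   counts (columns \code{sample_id}, \code{group}, \code{locus},
#'   \code{parent}, \code{count}); empty when unavailable.
#' @export
setClass("PrivateAlleleMatrix",
  representation(loci = "character", groups = "list",
                 counts = "data.frame", individualCounts = "data.frame"),
  validity = function(object) {
    cn <- object@counts
    if (!all(c("locus", "group", "parent", "count") %in% names(cn)))
      return("counts needs columns locus, group, parent, count")
    if (nrow(cn)) {
      if (any(cn$count < 0)) return("counts must be non-negative")
      if (!all(cn$parent %in% c("DAM", "SIRE")))
        return("parent must be DAM or SIRE")
      if (!all(cn$group %in% names(object@groups)))
        return("counts reference unknown groups")
      if (!all(cn$locus %in% object@loci))
        return("counts reference loci absent from the locus list")
    }
    TRUE
  })

setMethod("show", "PrivateAlleleMatrix", function(object) {
  cat("PrivateAlleleMatrix: ", length(object@loci), " loci, groups: ",
      paste(names(object@groups), collapse = ", "), "\n", sep = "")
  for (p in c("DAM", "SIRE")) {
    tot <- groupTotals(object, p)
    cat("  ", p, "-private totals: ",
        paste(names(tot), tot, sep = " = ", collapse = ", "), "\n", sep = "")
  }
})

#' Result of a paired per-locus t test
#'
#' @slot t the paired t statistic (mean difference over its standard
#'   error); \code{Inf}/\code{-Inf} with \code{degenerate = TRUE} when
#'   the differences have zero variance but non-zero mean.
#' @slot df integer degrees of freedom (number of locus pairs minus one).
#' @slot p two-sided probability from the t distribution.
#' @slot meanDiff mean paired difference (second series minus first).
#' @slot normalityP Shapiro-Wilk probability on the differences
#'   (NA when not computable); advisory only.
#' @slot degenerate logical, TRUE when the zero-variance rule was applied.
#' @export
setClass("PairedTestResult",
  representation(t = "numeric", df = "integer", p = "numeric",
                 meanDiff = "numeric", normalityP = "numeric",
                 degenerate = "logical"),
  validity = function(object) {
    if (!is.na(object@p) && (object@p < 0 || object@p > 1))
      return("p must lie in [0, 1]")
    TRUE
  })

setMethod("show", "PairedTestResult", function(object) {
  cat(sprintf("Paired t test: t = %.4g, df = %d, p = %.4g (mean diff %.4g)\n",
              object@t, object@df, object@p, object@meanDiff))
  if (!is.na(object@normalityP))
    cat(sprintf("  Shapiro-Wilk on differences: p = %.4g\n", object@normalityP))
  if (object@degenerate) cat("  [degenerate: zero-variance differences]\n")
})

#' Functional-ploidy call for one sample
#'
#' @slot sampleId sample identifier.
#' @slot contentPg absolute DNA content in pg per nucleus (NA if the
#'   measurement was a ratio).
#' @slot ratioToStandard measured content as a ratio to a standard
#'   (NA if absolute).
#' @slot calledPloidy called functional ploidy (integer n-multiplier);
#'   NA for a no-call.
#' @slot margin relative distance between the best and the next-best
#'   candidate residual; larger is a more confident call.
#' @slot noCall logical, TRUE when the best residual exceeded tolerance.
#' @export
setClass("PloidyCall",
  representation(sampleId = "character", contentPg = "numeric",
                 ratioToStandard = "numeric", calledPloidy = "integer",
                 margin = "numeric", noCall = "logical"))

setMethod("show", "PloidyCall", function(object) {
  lab <- if (object@noCall) "no-call" else paste0(object@calledPloidy, "n")
  val <- if (!is.na(object@contentPg)) sprintf("%.3f pg", object@contentPg)
         else sprintf("ratio %.3f", object@ratioToStandard)
  cat(sprintf("PloidyCall [%s]: %s -> %s (margin %.3g)\n",
              object@sampleId, val, lab, object@margin))
})

#' Mechanism verdict with its evidence trail
#'
#' @slot verdict one of NORMAL, MATERNAL_SDM_PB2,
#'   MATERNAL_CLONE_APOMIXIS_OR_ENDOMITOSIS, POLYSPERMY, UNRESOLVED.
#' @slot evidence data.frame with columns \code{criterion},
#'   \code{outcome}, \code{detail}, in the order the exclusion argument
#'   was evaluated.
#' @export
setClass("MechanismVerdict",
  representation(verdict = "character", evidence = "data.frame"),
  validity = function(object) {
    if (!object@verdict %in% .VERDICTS)
      return(paste("verdict must be one of:", paste(.VERDICTS, collapse = ", ")))
    if (nrow(object@evidence) < 1L)
      return("a verdict must carry at least one evidence entry")
    if (!all(c("criterion", "outcome", "detail") %in% names(object@evidence)))
      return("evidence needs columns criterion, outcome, detail")
    TRUE
  })

setMethod("show", "MechanismVerdict", function(object) {
  cat("MechanismVerdict:", object@verdict, "\n")
  ev <- object@evidence
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %d. %s: %s (%s)\n", i, ev$criterion[i], ev$outcome[i],
                ev$detail[i]))
})

#' Densitometry calibration standards
#'
#' Internal standards of known DNA content used to convert integrated
#' optical density (IOD) of Feulgen-stained nuclei to picograms. The
#' defaults are the diploid and induced-triploid tench standards
#' (2.02 and 3.10 pg per nucleus).
#'
#' @param label,iod,pg vectors describing the standards: a text label,
#'   the measured mean IOD, and the known DNA content in pg.
#' @return data.frame with columns \code{label}, \code{iod}, \code{pg}.
#' @export
#' @examples
#' densitometryStandards(c("2n tench", "3n tench"), iod = c(100, 153.5),
#'                       pg = c(2.02, 3.10))
densitometryStandards <- function(label, iod, pg) {
  stopifnot(length(label) == length(iod), length(iod) == length(pg))
  if (any(iod <= 0)) stop("standard IOD values must be positive")
  if (any(pg <= 0)) stop("standard DNA contents must be positive")
  data.frame(label = as.character(label), iod = as.numeric(iod),
             pg = as.numeric(pg), stringsAsFactors = FALSE)
}
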