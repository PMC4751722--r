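# Exclusion logic: from the ploidy excess over a normal zygote and the
# genotype evidence (clonal identity to the dam; parental origin of the
# duplicated set) to a mechanism verdict.

#' Ploidy excess of an observed zygote over the normal expectation
#'
#' @slot observed observed functional ploidy.
#' @slot expectedNormal dam_ploidy/2 + sire_ploidy/2.
#' @slot excess observed - expectedNormal.
#' @slot damPloidy,sirePloidy the parental functional ploidies, kept so
#'   the gamete ploidies the excess is compared against are on record.
#' @export
setClass("PloidyExcess",
  representation(observed = "integer", expectedNormal = "integer",
                 excess = "integer", damPloidy = "integer",
                 sirePloidy = "integer"))

setMethod("show", "PloidyExcess", function(object) {
  cat(sprintf("PloidyExcess: observed %dn, expected %dn (normal), excess %d\n",
              object@observed, object@expectedNormal, object@excess))
})

#' @describeIn PloidyExcess-class Compute the excess for one offspring.
#'   An excess of 0 marks a normal zygote; an excess equal to the dam's
#'   gamete ploidy marks a maternal-duplication candidate; an excess
#'   equal to the sire's gamete ploidy marks a polyspermy candidate.
#' @param observed observed functional ploidy of the offspring.
#' @param damPloidy,sirePloidy even parental functional ploidies.
#' @return A \code{PloidyExcess} object.
#' @export
#' @examples
#' ploidyExcess(7, 4, 6)  # excess 2 = dam gamete ploidy: maternal candidate
ploidyExcess <- function(observed, damPloidy, sirePloidy) {
  if (damPloidy %% 2 != 0 || sirePloidy %% 2 != 0)
    stop("parental ploidies must be even")
  expected <- as.integer(damPloidy / 2 + sirePloidy / 2)
  new("PloidyExcess", observed = as.integer(observed),
      expectedNormal = expected,
      excess = as.integer(observed - expected),
      damPloidy = as.integer(damPloidy), sirePloidy = as.integer(sirePloidy))
}

#' Fraction of loci at which an offspring carries the dam's full genotype
#'
#' Clonal oocytes (apomixis, premeiotic endomitosis) transmit the dam's
#' complete multilocus genotype, so a clone's observed alleles must
#' contain every dam allele at every locus. Under presence-only
#' observation the conservative test per locus is: the offspring's
#' alleles, minus alleles attributable only to the sire, form a superset
#' of the dam's full allele set. Loci with a missing offspring genotype
#' count as non-identical.
#'
#' @param table a \code{\linkS4class{GenotypeTable}}.
#' @param offspringId sample id of the offspring to test.
#' @return Fraction in \[0, 1\] over the loci genotyped in the dam.
#' @export
maternalIdentityFraction <- function(table, offspringId) {
  stopifnot(is(table, "GenotypeTable"),
            offspringId %in% sampleInfo(table)$sample_id)
  dam <- damId(table); sire <- sireId(table)
  lc <- Filter(function(l) length(alleleSet(table, dam, l)) > 0, loci(table))
  if (!length(lc)) stop("no genotyped dam loci shared with the offspring")
  ok <- vapply(lc, function(l) {
    damSet <- alleleSet(table, dam, l)
    sireOnly <- setdiff(alleleSet(table, sire, l), damSet)
    obs <- alleleSet(table, offspringId, l)
    all(damSet %in% setdiff(obs, sireOnly))
  }, logical(1))
  mean(ok)
}

#' Dropout-tolerant clonal-identity threshold
#'
#' A clonal offspring fails the per-locus dam-coverage test only when
#' allele dropout removes a dam allele, which happens at a locus with
#' probability 1 - (1 - dropout)^a for a dam alleles. The tolerant
#' threshold admits the expected number of dropout-broken loci (rounded
#' up): threshold = (L - ceiling(L * (1 - (1 - dropout)^a))) / L. With
#' dropout 0 this is exactly 1 (the strict default).
#'
#' @param nLoci number of loci tested.
#' @param dropout per-allele dropout probability.
#' @param allelesPerLocus typical count of distinct dam alleles per
#'   locus (default 4, a fully heterozygous tetraploid locus).
#' @return Threshold in (0, 1\] for \code{\link{inferMechanism}}.
#' @export
#' @examples
#' dropoutIdentityThreshold(8, 0.02)  # 7/8: tolerate one broken locus
dropoutIdentityThreshold <- function(nLoci, dropout, allelesPerLocus = 4) {
  stopifnot(nLoci >= 1, dropout >= 0, dropout < 1)
  expectedBroken <- nLoci * (1 - (1 - dropout)^allelesPerLocus)
  (nLoci - ceiling(expectedBroken)) / nLoci
}

.evRow <- function(criterion, outcome, detail) {
  data.frame(criterion = criterion, outcome = outcome, detail = detail,
             stringsAsFactors = FALSE)
}

.hypSupported <- function(hyp, which) {
  if (is.null(hyp)) return(NA)
  isTRUE(hyp$supported[hyp$hypothesis == which])
}

#' Infer the polyploidization mechanism for one offspring
#'
#' Implements the exclusion argument as an explicit decision sequence:
#' (1) zero excess is a normal zygote; (2) an excess matching the sire's
#' gamete ploidy (and not the dam's) is polyspermy — conversely, when
#' the sire's gamete ploidy cannot produce the excess, polyspermy is
#' excluded arithmetically; (3) an excess matching the dam's gamete
#' ploidy is maternal duplication: full genotype identity with the dam
#' (identity fraction at or above the threshold) indicates a clonal
#' oocyte (apomixis or premeiotic endomitosis, indistinguishable from
#' genotypes), while non-identity (recombination occurred) together with
#' a supported increase in dam-private alleles (H1) indicates
#' polar-body retention (recombination-bearing spontaneous duplication
#' of the maternal set, labelled PB2 for meiosis II); (4) anything else,
#' or conflicting evidence, is UNRESOLVED. When the two parental gamete
#' ploidies are equal the excess alone cannot point to a parent and the
#' verdict falls to the genotype evidence (H1 vs H2) rather than
#' guessing.
#'
#' @param excess a \code{\linkS4class{PloidyExcess}}.
#' @param identityFraction maternal identity fraction of the offspring
#'   (see \code{\link{maternalIdentityFraction}}).
#' @param hyp hypothesis table from \code{\link{testHypotheses}} for the
#'   offspring's group, or NULL when no battery could be run.
#' @param identityThreshold minimum identity fraction to call a clone
#'   (default 1.0, exact identity at all loci; lower it for
#'   dropout-tolerant runs).
#' @return A \code{\linkS4class{MechanismVerdict}}.
#' @export
inferMechanism <- function(excess, identityFraction, hyp = NULL,
                           identityThreshold = 1.0) {
  stopifnot(is(excess, "PloidyExcess"))
  damGam <- excess@damPloidy %/% 2L
  sireGam <- excess@sirePloidy %/% 2L
  ev <- .evRow("ploidy excess",
               sprintf("observed %dn - expected %dn = %d",
                       excess@observed, excess@expectedNormal,
                       excess@excess),
               sprintf("dam gamete ploidy %d, sire gamete ploidy %d",
                       damGam, sireGam))
  h1 <- .hypSupported(hyp, "H1_DAM"); h2 <- .hypSupported(hyp, "H2_SIRE")
  finish <- function(verdict, ...) {
    new("MechanismVerdict", verdict = verdict,
        evidence = rbind(ev, ...))
  }
  if (excess@excess == 0L)
    return(finish("NORMAL",
                  .evRow("excess = 0", "normal zygote",
                         "reduced oocyte + monospermic fertilization")))
  maternalBranch <- function(rows) {
    rows <- rbind(rows, .evRow(
      "maternal identity",
      sprintf("identity fraction %.3f vs threshold %.3f",
              identityFraction, identityThreshold),
      "clonal oocytes are genotype-identical to the dam"))
    if (identityFraction >= identityThreshold)
      return(finish("MATERNAL_CLONE_APOMIXIS_OR_ENDOMITOSIS", rows))
    rows <- rbind(rows, .evRow(
      "dam-private allele increase (H1)",
      if (isTRUE(h1)) "supported" else
        if (is.na(h1)) "unavailable" else "not supported",
      "polar-body retention (recombination-bearing SDM) requires H1"))
    if (isTRUE(h1)) return(finish("MATERNAL_SDM_PB2", rows))
    finish("UNRESOLVED", rows,
           .evRow("conclusion", "conflict",
                  paste("maternal-sized excess without clonal identity or",
                        "a supported dam-private increase")))
  }
  if (damGam == sireGam) {
    rows <- .evRow("gamete ploidies equal",
                   "excess alone cannot identify the parent",
                   "falling back to genotype evidence (H1 vs H2)")
    if (excess@excess == damGam) {
      if (isTRUE(h1) && !isTRUE(h2)) return(maternalBranch(rows))
      if (isTRUE(h2) && !isTRUE(h1))
        return(finish("POLYSPERMY", rows,
                      .evRow("sire-private allele increase (H2)",
                             "supported",
                             "extra set of paternal origin")))
      return(finish("UNRESOLVED", rows,
                    .evRow("genotype evidence",
                           "inconclusive",
                           "neither H1 nor H2 uniquely supported")))
    }
    return(finish("UNRESOLVED", rows,
                  .evRow("excess", "matches no single gamete ploidy", "")))
  }
  if (excess@excess == sireGam)
    return(finish("POLYSPERMY",
                  .evRow("excess = sire gamete ploidy",
                         "one extra spermatozoon accounts for the excess",
                         sprintf("%d + %d = %dn", excess@expectedNormal,
                                 sireGam, excess@observed))))
  if (excess@excess == damGam)
    return(maternalBranch(.evRow(
      "excess = dam gamete ploidy",
      "unreduced oocyte accounts for the excess",
      sprintf("%d + %d = %dn (polyspermy excluded: sire gamete ploidy %d cannot produce excess %d)",
              excess@damPloidy, sireGam, excess@observed, sireGam,
              excess@excess))))
  finish("UNRESOLVED",
         .evRow("excess", "matches no gamete ploidy",
                sprintf("excess %d is neither %d (dam) nor %d (sire)",
                        excess@excess, damGam, sireGam)))
}

#' Classify every offspring of a cross and summarize the mechanism
#'
#' Runs the full inference chain: offspring are grouped by called
#' functional ploidy; those at the normal expectation form the euploid
#' reference group; for each anomalous-ploidy group a size-matched
#' reference subset (first euploid siblings in table order, mirroring
#' the equal-group design) is drawn, the private-allele battery is run,
#' and every anomalous offspring receives a mechanism verdict. The
#' procedure is deterministic given its inputs.
#'
#' @param table a \code{\linkS4class{GenotypeTable}}.
#' @param ploidyCalls data.frame with columns \code{sample} and
#'   \code{called_ploidy} (as from \code{\link{callPloidyBatch}});
#'   every offspring must be covered, no-calls are dropped with a
#'   warning.
#' @param damPloidy,sirePloidy parental functional ploidies; default to
#'   the table's parental \code{ploidy_label}s.
#' @param alpha significance level of the battery.
#' @param identityThreshold see \code{\link{inferMechanism}}.
#' @return A list: \code{verdicts} (data.frame \code{sample},
#'   \code{called_ploidy}, \code{verdict}, \code{identity_fraction}),
#'   \code{verdictObjects} (named list of
#'   \code{\linkS4class{MechanismVerdict}}), \code{tests} and
#'   \code{matrices} (per anomalous group), and \code{summary} (list
#'   with \code{expected_normal}, \code{n_normal}, \code{anomalous}
#'   counts, \code{cross_verdict} — the modal anomalous verdict — and a
#'   human-readable \code{message}).
#' @export
classifyCross <- function(table, ploidyCalls, damPloidy = NULL,
                          sirePloidy = NULL, alpha = 0.05,
                          identityThreshold = 1.0) {
  stopifnot(is(table, "GenotypeTable"))
  s <- sampleInfo(table)
  if (is.null(damPloidy))
    damPloidy <- s$ploidy_label[s$role == "DAM"]
  if (is.null(sirePloidy))
    sirePloidy <- s$ploidy_label[s$role == "SIRE"]
  if (is.na(damPloidy) || is.na(sirePloidy))
    stop("parental ploidies unavailable: supply damPloidy/sirePloidy")
  offs <- offspringIds(table)
  calls <- ploidyCalls[match(offs, ploidyCalls$sample), , drop = FALSE]
  if (any(is.na(calls$sample)))
    stop("ploidy calls missing for offspring: ",
         paste(offs[is.na(calls$sample)], collapse = ", "))
  dropped <- offs[is.na(calls$called_ploidy)]
  if (length(dropped)) {
    warning(length(dropped), " offspring with ploidy no-calls dropped: ",
            paste(dropped, collapse = ", "))
    keep <- !is.na(calls$called_ploidy)
    offs <- offs[keep]; calls <- calls[keep, , drop = FALSE]
  }
  expected <- as.integer(damPloidy / 2 + sirePloidy / 2)
  normalIds <- offs[calls$called_ploidy == expected]
  anomalous <- split(offs[calls$called_ploidy != expected],
                     calls$called_ploidy[calls$called_ploidy != expected])

  verdictObjects <- list(); tests <- list(); matrices <- list()
  rows <- lapply(normalIds, function(id) {
    v <- inferMechanism(ploidyExcess(expected, damPloidy, sirePloidy),
                        identityFraction = NA_real_)
    verdictObjects[[id]] <<- v
    data.frame(sample = id, called_ploidy = expected, verdict = v@verdict,
               identity_fraction = NA_real_, stringsAsFactors = FALSE)
  })
  for (p in names(anomalous)) {
    ids <- anomalous[[p]]
    pInt <- as.integer(p)
    grpLab <- paste0(pInt, "n"); refLab <- paste0(expected, "n")
    hyp <- NULL
    if (length(normalIds)) {
      refIds <- normalIds[seq_len(min(length(ids), length(normalIds)))]
      mat <- suppressMessages(countPrivateAlleles(
        table, setNames(list(refIds, ids), c(refLab, grpLab))))
      matrices[[grpLab]] <- mat
      hyp <- suppressWarnings(testHypotheses(mat, alpha = alpha))
      tests[[grpLab]] <- hyp
    }
    for (id in ids) {
      idf <- maternalIdentityFraction(table, id)
      v <- inferMechanism(ploidyExcess(pInt, damPloidy, sirePloidy),
                          identityFraction = idf, hyp = hyp,
                          identityThreshold = identityThreshold)
      verdictObjects[[id]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        sample = id, called_ploidy = pInt, verdict = v@verdict,
        identity_fraction = idf, stringsAsFactors = FALSE)
    }
  }
  verdicts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), called_ploidy = integer(0),
               verdict = character(0), identity_fraction = numeric(0),
               stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  anomV <- verdicts$verdict[verdicts$called_ploidy != expected]
  if (length(anomV)) {
    tab <- table(anomV)
    crossVerdict <- names(tab)[which.max(tab)]
    msg <- sprintf("%d anomalous offspring; modal mechanism: %s",
                   length(anomV), crossVerdict)
  } else {
    crossVerdict <- "NORMAL"
    msg <- "no spontaneous polyploids detected"
  }
  list(verdicts = verdicts, verdictObjects = verdictObjects,
       tests = tests, matrices = matrices,
       summary = list(
         expected_normal = expected, n_normal = length(normalIds),
         anomalous = vapply(anomalous, length, integer(1)),
         cross_verdict = crossVerdict, message = msg))
}
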