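# Orchestration: file-level commands chaining the modules. These are the
# package's command surface; inst/scripts/ploidy-origin.R wraps them for
# shell use.

#' Simulate a cross and write its files
#'
#' Writes \code{genotypes.tsv} (long genotype dialect),
#' \code{labels.tsv} (\code{sample}, \code{true_mechanism},
#' \code{true_ploidy}), \code{measurements.tsv} (\code{sample},
#' \code{dna_pg}: mean DNA content over \code{nNuclei} simulated nuclei
#' per individual) and \code{manifest.json} (config echo, seed, package
#' version). Reruns with the same config are byte-identical.
#'
#' @param config a \code{\linkS4class{CrossConfig}}.
#' @param outDir output directory (created if needed).
#' @param perSetPg pg DNA per functional haploid set for the simulated
#'   cytometry; the default is the per-set content implied by the
#'   pentaploid reference measurement (8.98 pg / 5).
#' @param cv,nNuclei cytometry noise model, see
#'   \code{\link{simulateDnaContent}}.
#' @param nNormalSiblings when > 0, simulate the study-style mixed
#'   design via \code{\link{simulateMixedCross}}: this many euploid
#'   siblings alongside the \code{config@nOffspring} offspring of the
#'   configured mechanism.
#' @return Invisibly, the list from \code{\link{simulateCross}} plus
#'   \code{files}.
#' @export
cmdSimulate <- function(config, outDir, perSetPg = 1.796, cv = 0.02,
                        nNuclei = 3000, nNormalSiblings = 0) {
  stopifnot(is(config, "CrossConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (nNormalSiblings > 0)
    simulateMixedCross(config, nNormal = nNormalSiblings,
                       nAnomalous = config@nOffspring)
  else simulateCross(config)
  files <- file.path(outDir, c("genotypes.tsv", "labels.tsv",
                               "measurements.tsv", "manifest.json"))
  names(files) <- c("genotypes", "labels", "measurements", "manifest")
  writeGenotypeTable(sim$table, files["genotypes"])
  lab <- sim$labels[order(sim$labels$sample), , drop = FALSE]
  con <- file(files["labels"], open = "wb")
  writeLines(c("sample\ttrue_mechanism\ttrue_ploidy",
               if (nrow(lab)) do.call(paste, c(lab, sep = "\t"))), con)
  close(con)
  s <- sampleInfo(sim$table)
  meas <- data.frame(
    sample = s$sample_id,
    dna_pg = vapply(s$ploidy_label, function(p)
      mean(simulateDnaContent(p, perSetPg, cv, nNuclei)), numeric(1)),
    stringsAsFactors = FALSE)
  con <- file(files["measurements"], open = "wb")
  writeLines(c("sample\tdna_pg",
               sprintf("%s\t%.6f", meas$sample, meas$dna_pg)), con)
  close(con)
  manifest <- list(
    tool = "ploidyOrigin",
    version = as.character(utils::packageVersion("ploidyOrigin")),
    seed = config@seed,
    config = list(damPloidy = config@damPloidy,
                  sirePloidy = config@sirePloidy, nLoci = config@nLoci,
                  allelePoolSize = config@allelePoolSize, r = config@r,
                  femaleModel = config@femaleModel, nSperm = config@nSperm,
                  nOffspring = config@nOffspring,
                  observationDropout = config@observationDropout),
    cytometry = list(perSetPg = perSetPg, cv = cv, nNuclei = nNuclei))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(sim, list(files = files)))
}

#' Analyze a cross from files and write a report
#'
#' Two input modes, exactly one active per run. Genotype mode
#' (\code{genotypePath} + \code{measurementPath}): calls ploidy for all
#' offspring, groups them, runs the private-allele battery of each
#' anomalous group against size-matched euploid siblings, and infers a
#' mechanism per offspring. Counts mode (\code{countsPath}): runs the
#' battery directly on a published per-locus private-allele count
#' matrix, without genotypes or ploidy calling.
#'
#' @param genotypePath,measurementPath genotype-mode inputs (long
#'   genotype TSV; measurement TSV).
#' @param countsPath counts-mode input (locus/group/parent/count TSV).
#' @param outDir output directory for \code{report.json} and
#'   \code{summary.tsv}.
#' @param perSetPg,candidates,tolerance ploidy-calling parameters
#'   (genotype mode).
#' @param damPloidy,sirePloidy parental functional ploidies; genotype
#'   mode defaults to the parental labels absent from the files, so
#'   supply them when the TSV carries none.
#' @param alpha,identityThreshold battery and classifier thresholds.
#' @return Invisibly, the report list (also written as JSON).
#' @export
cmdAnalyze <- function(genotypePath = NULL, measurementPath = NULL,
                       countsPath = NULL, outDir,
                       perSetPg = 1.796, candidates = c(5L, 7L, 8L),
                       tolerance = 0.15, damPloidy = NULL,
                       sirePloidy = NULL, alpha = 0.05,
                       identityThreshold = 1.0) {
  genoMode <- !is.null(genotypePath)
  if (genoMode == !is.null(countsPath))
    stop("exactly one input mode: genotypePath(+measurementPath) or countsPath")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (genoMode) {
    if (is.null(measurementPath))
      stop("genotype mode needs a measurementPath")
    tab <- readGenotypeTable(genotypePath)
    meas <- readMeasurementTable(measurementPath)
    # parental ploidies are analysis inputs; only offspring are called
    meas <- meas[meas$sample %in% offspringIds(tab), , drop = FALSE]
    batch <- callPloidyBatch(meas, perSetPg, candidates, tolerance,
                             isRatio = attr(meas, "measure") ==
                               "ratio_to_standard")
    cls <- classifyCross(tab, batch$calls, damPloidy = damPloidy,
                         sirePloidy = sirePloidy, alpha = alpha,
                         identityThreshold = identityThreshold)
    validation <- validateCrossTable(tab)
    report <- list(
      mode = "genotypes",
      ploidy_summary = batch$summary,
      validation = list(
        uninformative_loci = validation$uninformative_loci,
        n_non_parental = nrow(validation$non_parental),
        n_missing = nrow(validation$missing)),
      private_alleles = lapply(cls$matrices, function(m)
        list(loci = loci(m),
             dam_totals = as.list(groupTotals(m, "DAM")),
             sire_totals = as.list(groupTotals(m, "SIRE")))),
      tests = lapply(cls$tests, function(h)
        h[c("hypothesis", "supported", "t", "df", "p", "mean_diff",
            "fold_change")]),
      verdicts = cls$verdicts,
      summary = cls$summary)
    sumTab <- cls$verdicts
  } else {
    mat <- readCountMatrix(countsPath)
    hyp <- suppressWarnings(testHypotheses(mat, alpha = alpha))
    grp <- attr(hyp, "groups")
    report <- list(
      mode = "counts",
      private_alleles = list(
        loci = loci(mat),
        dam_totals = as.list(groupTotals(mat, "DAM")),
        sire_totals = as.list(groupTotals(mat, "SIRE"))),
      tests = hyp[c("hypothesis", "supported", "t", "df", "p",
                    "mean_diff", "fold_change")],
      summary = list(
        reference_group = unname(grp["ref"]),
        test_group = unname(grp["test"]),
        dam_fold_change = suppressWarnings(
          foldChange(mat, "DAM", grp["test"], grp["ref"]))))
    sumTab <- report$tests
  }
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write.table(sumTab, file.path(outDir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Render a report as deterministic plain text
#'
#' @param reportPath path to a \code{report.json} written by
#'   \code{\link{cmdAnalyze}} (or the report list itself).
#' @return Character vector of lines, invisibly; also printed.
#' @export
cmdReport <- function(reportPath) {
  report <- if (is.character(reportPath))
    jsonlite::read_json(reportPath, simplifyVector = TRUE) else reportPath
  lines <- c(sprintf("ploidyOrigin report (mode: %s)", report$mode))
  fmtTests <- function(tests, label = NULL) {
    out <- character(0)
    if (!is.null(label)) out <- sprintf("group %s:", label)
    for (i in seq_len(nrow(tests))) {
      r <- tests[i, ]
      if (r$hypothesis == "H3_BOTH") {
        out <- c(out, sprintf("  %s: %s", r$hypothesis,
                              if (r$supported) "supported" else
                                "not supported"))
      } else {
        out <- c(out, sprintf(
          "  %s: %s (t = %.4g, df = %d, p = %.4g, fold = %.3g)",
          r$hypothesis,
          if (r$supported) "increase supported" else "no increase",
          r$t, r$df, r$p, r$fold_change))
      }
    }
    out
  }
  if (identical(report$mode, "counts")) {
    lines <- c(lines,
               sprintf("dam-private totals: %s",
                       paste(names(report$private_alleles$dam_totals),
                             unlist(report$private_alleles$dam_totals),
                             sep = " = ", collapse = ", ")),
               fmtTests(as.data.frame(report$tests)))
  } else {
    ps <- as.data.frame(report$ploidy_summary)
    lines <- c(lines, "ploidy summary:",
               sprintf("  %sn: %d", ps$ploidy, ps$count))
    if (length(report$tests)) {
      for (g in names(report$tests))
        lines <- c(lines, fmtTests(as.data.frame(report$tests[[g]]), g))
    }
    v <- as.data.frame(report$verdicts)
    if (nrow(v)) {
      anom <- v[v$called_ploidy != report$summary$expected_normal, ,
                drop = FALSE]
      lines <- c(lines, sprintf("verdicts (%d offspring):", nrow(v)))
      if (nrow(anom))
        lines <- c(lines, sprintf("  %s (%dn): %s", anom$sample,
                                  anom$called_ploidy, anom$verdict))
      lines <- c(lines, sprintf("summary: %s", report$summary$message))
    } else {
      lines <- c(lines, "no offspring analyzed")
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
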