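# Private-allele coding and the paired per-locus test battery used to
# locate the parental origin of a spontaneous extra chromosome set.

#' Classify an allele against the two parental allele sets
#'
#' An allele observed in an offspring is \code{DAM_PRIVATE} if present in
#' the dam only, \code{SIRE_PRIVATE} if in the sire only, \code{SHARED}
#' if in both (uninformative for origin), and \code{NON_PARENTAL} if in
#' neither (artifact or mutation). The four classes are exhaustive and
#' mutually exclusive.
#'
#' @param allele integer allele length(s) to classify (vectorized).
#' @param damSet,sireSet non-empty integer vectors of parental alleles.
#' @return Character vector of classes, one per allele.
#' @export
#' @examples
#' classifyAllele(c(180, 184, 210), damSet = c(180, 184),
#'                sireSet = c(184, 196))
classifyAllele <- function(allele, damSet, sireSet) {
  if (!length(damSet) || !length(sireSet))
    stop("parental allele sets must be non-empty")
  inD <- allele %in% damSet
  inS <- allele %in% sireSet
  out <- ifelse(inD & inS, "SHARED",
         ifelse(inD, "DAM_PRIVATE",
         ifelse(inS, "SIRE_PRIVATE", "NON_PARENTAL")))
  out
}

#' Count private alleles per locus and offspring group
#'
#' For every grouped offspring and every locus, counts the distinct
#' dam-private and sire-private alleles observed (each private allele
#' "coded 1"; shared alleles carry no information and non-parental
#' alleles are excluded and reported via message). Group counts are the
#' sums over the group's members. Loci at which neither parent has a
#' private allele cannot contribute and are dropped with a message
#' (reducing the degrees of freedom of downstream tests) unless
#' \code{excludeUninformative = FALSE}.
#'
#' @param table a \code{\linkS4class{GenotypeTable}} with one dam and
#'   one sire.
#' @param groups named list mapping a group label (e.g. \code{"5n"},
#'   \code{"7n"}) to offspring sample ids.
#' @param excludeUninformative drop loci with no parent-private alleles.
#' @return A \code{\linkS4class{PrivateAlleleMatrix}}.
#' @export
countPrivateAlleles <- function(table, groups, excludeUninformative = TRUE) {
  stopifnot(is(table, "GenotypeTable"), is.list(groups),
            !is.null(names(groups)))
  known <- sampleInfo(table)$sample_id
  unknown <- setdiff(unlist(groups), known)
  if (length(unknown))
    stop("group members absent from the table: ",
         paste(unknown, collapse = ", "))
  if (length(unique(lengths(groups))) > 1L)
    warning("groups have unequal sizes; the fold change of group totals ",
            "is not directly interpretable")
  dam <- damId(table); sire <- sireId(table)
  lc <- loci(table)
  priv <- lapply(lc, function(l) {
    d <- alleleSet(table, dam, l); s <- alleleSet(table, sire, l)
    list(DAM = setdiff(d, s), SIRE = setdiff(s, d))
  })
  names(priv) <- lc
  informative <- vapply(priv, function(p)
    length(p$DAM) + length(p$SIRE) > 0L, logical(1))
  if (excludeUninformative && any(!informative)) {
    message("excluding ", sum(!informative),
            " uninformative locus/loci (parents share all alleles): ",
            paste(lc[!informative], collapse = ", "))
    lc <- lc[informative]
  }
  rows <- list(); nNonParental <- 0L
  for (gname in names(groups)) {
    for (id in groups[[gname]]) {
      for (l in lc) {
        obs <- alleleSet(table, id, l)
        damFull <- alleleSet(table, dam, l)
        sireFull <- alleleSet(table, sire, l)
        nNonParental <- nNonParental +
          sum(!(obs %in% damFull) & !(obs %in% sireFull))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, group = gname, locus = l,
          parent = c("DAM", "SIRE"),
          count = c(sum(obs %in% priv[[l]]$DAM),
                    sum(obs %in% priv[[l]]$SIRE)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nNonParental > 0L)
    message(nNonParental, " non-parental allele observation(s) excluded ",
            "from private-allele counts")
  indiv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), group = character(0),
               locus = character(0), parent = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  agg <- if (nrow(indiv)) {
    a <- stats::aggregate(count ~ locus + group + parent, indiv, sum)
    a[order(match(a$locus, lc), a$group, a$parent), , drop = FALSE]
  } else {
    data.frame(locus = character(0), group = character(0),
               parent = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  rownames(agg) <- NULL
  new("PrivateAlleleMatrix", loci = lc, groups = groups,
      counts = agg, individualCounts = indiv)
}

#' Paired per-locus t test
#'
#' With one pair of observations per locus, the differences are
#' d = y - x, the statistic is t = mean(d) / (sd(d) / sqrt(n)) with
#' n - 1 degrees of freedom, and the two-sided probability comes from
#' the t distribution. All-zero differences give exactly t = 0, p = 1;
#' zero variance with a non-zero mean is reported as an infinite t with
#' p = 0 and flagged degenerate. A Shapiro-Wilk probability on the
#' differences is attached when computable (advisory: the pipeline
#' warns on non-normality but never aborts).
#'
#' @param x,y numeric vectors of equal length >= 2, paired by locus.
#' @return A \code{\linkS4class{PairedTestResult}}.
#' @export
#' @examples
#' pairedT(c(4, 4, 4), c(5, 6, 7))  # d = (1, 2, 3): t = sqrt(12), df = 2
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 locus pairs")
  d <- y - x
  m <- mean(d); s <- sd(d)
  df <- n - 1L
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1; degen <- FALSE
    } else {
      t <- sign(m) * Inf; p <- 0; degen <- TRUE
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = df)
    degen <- FALSE
  }
  normP <- if (n >= 3L && s > 0) suppressWarnings(shapiroWilkCheck(d))
           else NA_real_
  new("PairedTestResult", t = t, df = df, p = p, meanDiff = m,
      normalityP = normP, degenerate = degen)
}

#' Shapiro-Wilk normality probability for paired differences
#'
#' Advisory check of the paired t test's normality assumption. Returns
#' NA (with a warning) when fewer than 3 differences are available or
#' the differences are constant, where the statistic is undefined.
#'
#' @param d numeric vector of paired differences.
#' @return The Shapiro-Wilk p-value, or NA when not computable. The W
#'   statistic is attached as attribute \code{"W"} when computed.
#' @export
shapiroWilkCheck <- function(d) {
  if (length(d) < 3L) {
    warning("Shapiro-Wilk needs at least 3 differences; not computable")
    return(NA_real_)
  }
  if (sd(d) == 0) {
    warning("constant differences; Shapiro-Wilk not computable (degenerate)")
    return(NA_real_)
  }
  sw <- shapiro.test(d)
  structure(unname(sw$p.value), W = unname(sw$statistic))
}

#' Fold change of group totals of private alleles
#'
#' Ratio of the two groups' totals of \code{parent}-private alleles
#' summed over loci (e.g. 63 dam-private alleles in the heptaploid group
#' over 35 in the pentaploid group = 1.8).
#'
#' @param matrix a \code{\linkS4class{PrivateAlleleMatrix}}.
#' @param parent \code{"DAM"} or \code{"SIRE"}.
#' @param groupNum,groupDen labels of the numerator and denominator
#'   groups.
#' @param digits optional rounding of the reported ratio; NULL = exact.
#' @return The ratio; NaN with a warning when the denominator total is 0.
#' @export
foldChange <- function(matrix, parent, groupNum, groupDen, digits = NULL) {
  tot <- groupTotals(matrix, parent)
  if (!all(c(groupNum, groupDen) %in% names(tot)))
    stop("unknown group label(s)")
  if (tot[[groupDen]] == 0) {
    warning("denominator group total is zero; fold change undefined")
    return(NaN)
  }
  fc <- tot[[groupNum]] / tot[[groupDen]]
  if (!is.null(digits)) fc <- round(fc, digits)
  unname(fc)
}

#' Test the three parental-origin hypotheses
#'
#' Runs the paired per-locus t test separately on the dam-private and
#' sire-private counts of a two-group matrix (reference group first,
#' e.g. the euploid siblings; test group second, e.g. the anomalous
#' ploidy group). H1 (duplicated material of maternal origin) is
#' supported when the dam-private counts increase significantly in the
#' test group (two-sided p < alpha and a positive mean difference);
#' H2 likewise for sire-private counts (paternal origin); H3 (both
#' parents) holds iff H1 and H2 both hold.
#'
#' @param matrix a \code{\linkS4class{PrivateAlleleMatrix}} with at
#'   least two groups.
#' @param alpha significance level (default 0.05).
#' @param refGroup,testGroup group labels; default to the first and
#'   second group of the matrix.
#' @return data.frame with one row per hypothesis (\code{H1_DAM},
#'   \code{H2_SIRE}, \code{H3_BOTH}) and columns \code{supported},
#'   \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{fold_change}; the underlying
#'   \code{\linkS4class{PairedTestResult}} objects are attached as
#'   attribute \code{"tests"}.
#' @export
testHypotheses <- function(matrix, alpha = 0.05, refGroup = NULL,
                           testGroup = NULL) {
  gn <- groupNames(matrix)
  if (length(gn) < 2L) stop("matrix must have at least two groups")
  if (is.null(refGroup)) refGroup <- gn[1L]
  if (is.null(testGroup)) testGroup <- gn[2L]
  stopifnot(all(c(refGroup, testGroup) %in% gn))
  res <- list(); sup <- c(DAM = FALSE, SIRE = FALSE)
  rows <- list()
  for (parent in c("DAM", "SIRE")) {
    m <- lociCounts(matrix, parent)
    tt <- pairedT(m[, refGroup], m[, testGroup])
    if (!is.na(tt@normalityP) && tt@normalityP < 0.05)
      warning(parent, "-private paired differences deviate from ",
              "normality (Shapiro-Wilk p = ", signif(tt@normalityP, 3),
              "); the paired t test assumption is questionable")
    fc <- suppressWarnings(foldChange(matrix, parent, testGroup, refGroup))
    sup[parent] <- !is.na(tt@p) && tt@p < alpha && tt@meanDiff > 0
    res[[parent]] <- tt
    rows[[parent]] <- data.frame(
      hypothesis = if (parent == "DAM") "H1_DAM" else "H2_SIRE",
      supported = unname(sup[parent]), t = tt@t, df = tt@df, p = tt@p,
      mean_diff = tt@meanDiff, fold_change = fc, stringsAsFactors = FALSE)
  }
  out <- rbind(rows$DAM, rows$SIRE,
               data.frame(hypothesis = "H3_BOTH",
                          supported = unname(sup["DAM"] && sup["SIRE"]),
                          t = NA_real_, df = NA_integer_, p = NA_real_,
                          mean_diff = NA_real_, fold_change = NA_real_,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "tests") <- res
  attr(out, "groups") <- c(ref = refGroup, test = testGroup)
  out
}

#' Calibrate the heterozygosity-restoration parameter r from a fold change
#'
#' Inverts the simulator: for each grid value of r, simulates a cross
#' with two sibling cohorts sharing the same parents — one normal, one
#' with second-polar-body retention at that r — and computes the
#' expected fold change of dam-private alleles; returns the grid value
#' whose simulated fold is closest to the target. A target outside the
#' simulated range is answered with the nearest boundary and a flag.
#'
#' @param targetFold observed fold change to invert, in \[1, 2\].
#' @param config a \code{\linkS4class{CrossConfig}} describing the
#'   cross (its \code{femaleModel}/\code{nSperm} are ignored here).
#' @param grid r values to scan.
#' @param nOffspring cohort size per arm; larger = smoother curve.
#' @return list with \code{r} (estimate), \code{curve} (data.frame
#'   \code{r}, \code{fold}) and \code{boundary} (logical flag).
#' @export
calibrateR <- function(targetFold, config, grid = seq(0, 1, by = 0.1),
                       nOffspring = 500) {
  stopifnot(is(config, "CrossConfig"))
  folds <- vapply(seq_along(grid), function(i) {
    cfg <- config
    cfg@r <- grid[i]
    cfg@femaleModel <- "PB2_RETENTION"
    cfg@nSperm <- 1L
    cfg@seed <- as.integer((config@seed + 101L * i) %% .Machine$integer.max)
    sim <- simulateMixedCross(cfg, nNormal = nOffspring,
                              nAnomalous = nOffspring)
    mat <- suppressMessages(countPrivateAlleles(sim$table, sim$groups))
    suppressWarnings(foldChange(mat, "DAM", "anomalous", "normal"))
  }, numeric(1))
  best <- which.min(abs(folds - targetFold))
  boundary <- targetFold < min(folds) - 1e-9 || targetFold > max(folds) + 1e-9
  list(r = grid[best], curve = data.frame(r = grid, fold = folds),
       boundary = boundary)
}

#' Read a private-allele count matrix from a TSV file
#'
#' Accepts the count-only layout (columns \code{locus}, \code{group},
#' \code{parent}, \code{count}) for studies that publish per-locus
#' private-allele counts rather than raw genotypes, enabling the full
#' statistical battery without genotype data.
#'
#' @param path path to the TSV file.
#' @return A \code{\linkS4class{PrivateAlleleMatrix}} (with empty group
#'   membership and individual counts).
#' @export
readCountMatrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "group", "parent", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("count matrix lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) stop("count matrix file is empty")
  if (any(is.na(raw$count)) || any(raw$count < 0))
    stop("counts must be non-negative integers")
  raw$locus <- as.character(raw$locus)
  raw$group <- as.character(raw$group)
  raw$parent <- as.character(raw$parent)
  raw$count <- as.integer(raw$count)
  groups <- setNames(vector("list", length(unique(raw$group))),
                     unique(raw$group))
  groups[] <- list(character(0))
  new("PrivateAlleleMatrix", loci = unique(raw$locus), groups = groups,
      counts = raw[need],
      individualCounts = data.frame(sample_id = character(0),
                                    group = character(0),
                                    locus = character(0),
                                    parent = character(0),
                                    count = integer(0),
                                    stringsAsFactors = FALSE))
}

#' Write a private-allele count matrix to a TSV file
#'
#' Deterministic row order (locus in matrix order, then group, then
#' parent); round-trips with \code{\link{readCountMatrix}}.
#'
#' @param matrix a \code{\linkS4class{PrivateAlleleMatrix}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCountMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "PrivateAlleleMatrix"))
  cn <- matrix@counts
  cn <- cn[order(match(cn$locus, matrix@loci), cn$group, cn$parent), ,
           drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("locus\tgroup\tparent\tcount", con)
  if (nrow(cn)) writeLines(do.call(paste, c(cn, sep = "\t")), con)
  invisible(path)
}
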