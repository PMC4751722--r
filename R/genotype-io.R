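#' Read a genotype table from a tab-separated file
#'
#' Reads the long canonical dialect (columns \code{sample}, \code{role},
#' \code{locus}, \code{allele}; one observed allele per row) or, with
#' \code{format = "wide"}, a wide dialect where an \code{alleles} column
#' holds semicolon-separated fragment lengths. Rows for the same
#' (sample, locus) are merged into one allele set; duplicate
#' (sample, locus, allele) rows are collapsed silently with a warning,
#' since genotypes are presence-only sets.
#'
#' @param path path to a UTF-8 TSV file with a header line.
#' @param format \code{"long"} (canonical) or \code{"wide"}.
#' @return A validated \code{\linkS4class{GenotypeTable}}.
#' @seealso \code{\link{writeGenotypeTable}}, \code{\link{validateCrossTable}}
#' @export
readGenotypeTable <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  need <- if (format == "long") c("sample", "role", "locus", "allele")
          else c("sample", "role", "locus", "alleles")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("genotype file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (format == "wide") {
    parts <- strsplit(raw$alleles, ";", fixed = TRUE)
    raw <- data.frame(
      sample = rep(raw$sample, lengths(parts)),
      role = rep(raw$role, lengths(parts)),
      locus = rep(raw$locus, lengths(parts)),
      allele = trimws(unlist(parts)), stringsAsFactors = FALSE)
  }
  num <- suppressWarnings(as.numeric(raw$allele))
  bad <- which(is.na(num) | num %% 1 != 0)
  if (length(bad))
    stop("non-integer allele value in row ", bad[1], ": '",
         raw$allele[bad[1]], "'")
  raw$allele <- as.integer(raw$allele)
  ndup <- sum(duplicated(raw[c("sample", "locus", "allele")]))
  if (ndup > 0)
    warning(ndup, " duplicate (sample, locus, allele) row(s) merged")
  samples <- unique(raw[c("sample", "role")])
  names(samples) <- c("sample_id", "role")
  genos <- raw[c("sample", "locus", "allele")]
  names(genos) <- c("sample_id", "locus", "allele")
  GenotypeTable(samples = samples, genotypes = genos)
}

#' Write a genotype table in the canonical long dialect
#'
#' Rows are ordered by sample (table order), then locus, then ascending
#' allele, so two writes of the same table are byte-identical.
#'
#' @param table a \code{\linkS4class{GenotypeTable}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypeTable <- function(table, path) {
  stopifnot(is(table, "GenotypeTable"))
  s <- sampleInfo(table)
  g <- genotypes(table)
  g$role <- s$role[match(g$sample_id, s$sample_id)]
  ord <- order(match(g$sample_id, s$sample_id),
               match(g$locus, loci(table)), g$allele)
  out <- g[ord, c("sample_id", "role", "locus", "allele")]
  names(out) <- c("sample", "role", "locus", "allele")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' Validate a cross table for the private-allele analysis
#'
#' Report-only checks (the input is never modified): loci at which the
#' parents share every allele are uninformative for private-allele
#' counting and flagged for exclusion; offspring alleles present in
#' neither parent are flagged as non-parental (genotyping artifact or
#' mutation); missing (sample, locus) genotypes are listed.
#'
#' @param table a \code{\linkS4class{GenotypeTable}}.
#' @return A list with elements \code{uninformative_loci} (character),
#'   \code{non_parental} (data.frame sample_id/locus/allele) and
#'   \code{missing} (data.frame sample_id/locus), plus \code{clean},
#'   TRUE when all three are empty.
#' @export
validateCrossTable <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  dam <- damId(table); sire <- sireId(table)
  lc <- loci(table)
  uninformative <- character(0)
  for (l in lc) {
    d <- alleleSet(table, dam, l); s <- alleleSet(table, sire, l)
    if (length(d) && length(s) && setequal(d, s))
      uninformative <- c(uninformative, l)
  }
  g <- genotypes(table)
  offs <- offspringIds(table)
  np <- g[g$sample_id %in% offs, , drop = FALSE]
  keep <- logical(nrow(np))
  for (i in seq_len(nrow(np))) {
    l <- np$locus[i]
    keep[i] <- !(np$allele[i] %in% alleleSet(table, dam, l)) &&
               !(np$allele[i] %in% alleleSet(table, sire, l))
  }
  non_parental <- np[keep, c("sample_id", "locus", "allele"), drop = FALSE]
  rownames(non_parental) <- NULL
  all_ids <- sampleInfo(table)$sample_id
  grid <- expand.grid(sample_id = all_ids, locus = lc,
                      stringsAsFactors = FALSE)
  have <- unique(g[c("sample_id", "locus")])
  missing <- grid[!do.call(paste, grid) %in% do.call(paste, have), ,
                  drop = FALSE]
  rownames(missing) <- NULL
  list(uninformative_loci = uninformative, non_parental = non_parental,
       missing = missing,
       clean = !length(uninformative) && !nrow(non_parental) &&
               !nrow(missing))
}

#' Read a DNA-content measurement table
#'
#' Expects a TSV with a \code{sample} column plus either \code{dna_pg}
#' (absolute pg per nucleus) or \code{ratio_to_standard} (dimensionless).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{sample} and \code{value}, plus
#'   an attribute \code{measure} naming which dialect was read.
#' @export
readMeasurementTable <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample" %in% names(raw))
    stop("measurement file lacks required column: sample")
  col <- intersect(c("dna_pg", "ratio_to_standard"), names(raw))
  if (!length(col))
    stop("measurement file needs a dna_pg or ratio_to_standard column")
  out <- data.frame(sample = as.character(raw$sample),
                    value = as.numeric(raw[[col[1]]]),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$value) | out$value <= 0))
    stop("measurements must be positive numbers")
  attr(out, "measure") <- col[1]
  out
}
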