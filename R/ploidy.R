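# Ploidy calling from DNA content and the fertilization arithmetic for
# zygote ploidy / chromosome number under each gamete model.

#' Call functional ploidy from a DNA-content measurement
#'
#' Nearest-candidate rule: the call is the candidate ploidy minimizing
#' |measurement - candidate * perSetReference|. The call is rejected
#' (no-call) when the relative residual |m - c*ref| / (c*ref) of the best
#' candidate exceeds \code{tolerance}. Ties are broken toward the lower
#' ploidy with a warning. The rule is scale-invariant, so
#' \code{measurement} may be absolute pg (with \code{perSetReference} in
#' pg per functional set) or a ratio to a standard (with the reference on
#' the same ratio scale).
#'
#' @param measurement positive DNA-content measurement for one sample.
#' @param perSetReference DNA content of one functional haploid set, in
#'   the units of \code{measurement}.
#' @param candidates integer vector of candidate functional ploidies.
#' @param tolerance maximum relative residual accepted for a call.
#' @param sampleId sample label carried into the result.
#' @param isRatio set TRUE when \code{measurement} is a ratio to a
#'   standard rather than absolute pg.
#' @return A \code{\linkS4class{PloidyCall}}.
#' @export
#' @examples
#' callPloidy(8.98, perSetReference = 1.796, candidates = c(5, 7))   # 5n
#' callPloidy(15.02, perSetReference = 2.146, candidates = c(5, 7))  # 7n
callPloidy <- function(measurement, perSetReference, candidates,
                       tolerance = 0.15, sampleId = NA_character_,
                       isRatio = FALSE) {
  if (!length(candidates)) stop("candidates must be non-empty")
  if (perSetReference <= 0) stop("perSetReference must be positive")
  if (is.na(measurement) || measurement <= 0)
    stop("measurement must be positive")
  candidates <- sort(unique(as.integer(candidates)))
  expected <- candidates * perSetReference
  resid <- abs(measurement - expected)
  best <- which(resid == min(resid))
  if (length(best) > 1L) {
    warning("tie between candidate ploidies ",
            paste(candidates[best], collapse = " and "),
            "; calling the lower")
    best <- best[1L]
  }
  relResid <- resid[best] / expected[best]
  noCall <- relResid > tolerance
  margin <- if (length(candidates) > 1L)
    (sort(resid)[2L] - resid[best]) / expected[best] else Inf
  new("PloidyCall",
      sampleId = as.character(sampleId),
      contentPg = if (isRatio) NA_real_ else measurement,
      ratioToStandard = if (isRatio) measurement else NA_real_,
      calledPloidy = if (noCall) NA_integer_ else candidates[best],
      margin = margin, noCall = noCall)
}

#' Convert Feulgen densitometry IOD to genome size
#'
#' The integrated optical density (IOD) of a Feulgen-stained nucleus is
#' proportional to its DNA content, so each calibration standard of
#' known content implies an estimate (sample_iod / standard_iod) *
#' standard_pg; the result is the mean over standards. Linear in
#' \code{sampleIod}.
#'
#' @param sampleIod mean IOD of the sample's nuclei (> 0).
#' @param standards data.frame from \code{\link{densitometryStandards}}.
#' @return Estimated DNA content in pg per nucleus.
#' @export
#' @examples
#' std <- densitometryStandards(c("2n tench", "3n tench"),
#'                              iod = c(100, 153.5), pg = c(2.02, 3.10))
#' estimateGenomeSize(100, std[1, ])  # 2.02 pg by construction
estimateGenomeSize <- function(sampleIod, standards) {
  if (any(sampleIod <= 0)) stop("sample IOD must be positive")
  if (!all(c("iod", "pg") %in% names(standards)) || !nrow(standards))
    stop("standards must be a non-empty densitometryStandards() table")
  if (any(standards$iod <= 0)) stop("standard IOD must be positive")
  mean(sampleIod / standards$iod * standards$pg)
}

.oocyteSets <- function(damPloidy, femaleModel) {
  if (femaleModel == "NORMAL") damPloidy / 2 else damPloidy
}

#' Predict zygote functional ploidy for a cross/mechanism combination
#'
#' The oocyte contributes half the dam's homolog sets under normal
#' meiosis and all of them when unreduced (second-polar-body retention,
#' or a clonal oocyte from apomixis/endomitosis); each spermatozoon
#' contributes half the sire's sets. For the 4n x 6n study cross this
#' yields 5n (normal), 7n (PB2 retention) and 8n (dispermic).
#'
#' @param damPloidy,sirePloidy even functional ploidies of the parents.
#' @param femaleModel one of \code{gameteModels()}.
#' @param nSperm 1 (monospermic) or 2 (dispermic).
#' @return Integer zygote functional ploidy.
#' @export
#' @examples
#' predictZygotePloidy(4, 6, "NORMAL", 1)         # 5
#' predictZygotePloidy(4, 6, "PB2_RETENTION", 1)  # 7
#' predictZygotePloidy(4, 6, "NORMAL", 2)         # 8
predictZygotePloidy <- function(damPloidy, sirePloidy,
                                femaleModel = gameteModels(), nSperm = 1) {
  femaleModel <- match.arg(femaleModel)
  if (damPloidy %% 2 != 0 || sirePloidy %% 2 != 0)
    stop("parental ploidies must be even")
  if (!nSperm %in% 1:2) stop("nSperm must be 1 or 2")
  as.integer(.oocyteSets(damPloidy, femaleModel) + nSperm * sirePloidy / 2)
}

#' Predict zygote chromosome number
#'
#' Applies the \code{\link{predictZygotePloidy}} arithmetic to parental
#' chromosome counts: the oocyte carries half the dam's count (all of it
#' when unreduced), each spermatozoon half the sire's. Halves are rounded
#' half-up, since sturgeon chromosome counts are themselves approximate
#' (microchromosomes defy exact counting).
#'
#' @param damCount,sireCount parental somatic chromosome counts (> 0).
#' @param femaleModel one of \code{gameteModels()}.
#' @param nSperm 1 or 2.
#' @return Integer predicted zygote chromosome number.
#' @export
#' @examples
#' predictChromosomeNumber(245, 368, "PB2_RETENTION", 1)  # 245 + 184 = 429
predictChromosomeNumber <- function(damCount, sireCount,
                                    femaleModel = gameteModels(),
                                    nSperm = 1) {
  femaleModel <- match.arg(femaleModel)
  if (damCount <= 0 || sireCount <= 0)
    stop("chromosome counts must be positive")
  if (!nSperm %in% 1:2) stop("nSperm must be 1 or 2")
  halfUp <- function(x) floor(x + 0.5)
  oocyte <- if (femaleModel == "NORMAL") halfUp(damCount / 2) else damCount
  as.integer(oocyte + nSperm * halfUp(sireCount / 2))
}

#' Call ploidy for a batch of samples and summarize
#'
#' @param measurements data.frame with columns \code{sample} and
#'   \code{value} (as from \code{\link{readMeasurementTable}}), or a
#'   named numeric vector.
#' @param perSetReference,candidates,tolerance,isRatio as in
#'   \code{\link{callPloidy}}.
#' @return A list with \code{calls} (data.frame \code{sample},
#'   \code{value}, \code{called_ploidy}, \code{margin}, \code{no_call})
#'   and \code{summary} (data.frame \code{ploidy}, \code{count};
#'   no-calls tallied under ploidy NA).
#' @export
callPloidyBatch <- function(measurements, perSetReference, candidates,
                            tolerance = 0.15, isRatio = FALSE) {
  if (is.numeric(measurements))
    measurements <- data.frame(
      sample = if (is.null(names(measurements)))
        as.character(seq_along(measurements)) else names(measurements),
      value = as.numeric(measurements), stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "value") %in% names(measurements)))
  n <- nrow(measurements)
  calls <- data.frame(sample = measurements$sample,
                      value = measurements$value,
                      called_ploidy = rep(NA_integer_, n),
                      margin = rep(NA_real_, n),
                      no_call = rep(FALSE, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pc <- callPloidy(measurements$value[i], perSetReference, candidates,
                     tolerance, sampleId = measurements$sample[i],
                     isRatio = isRatio)
    calls$called_ploidy[i] <- pc@calledPloidy
    calls$margin[i] <- pc@margin
    calls$no_call[i] <- pc@noCall
  }
  tab <- table(calls$called_ploidy, useNA = "ifany")
  summary <- data.frame(ploidy = suppressWarnings(as.integer(names(tab))),
                        count = as.integer(tab), stringsAsFactors = FALSE)
  list(calls = calls, summary = summary)
}
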