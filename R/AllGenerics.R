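# Accessor generics: user code reads objects through these, never via slots.

#' @rdname GenotypeTable-class
#' @param x a \code{GenotypeTable} (or other object with samples).
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("damId", function(x) standardGeneric("damId"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("sireId", function(x) standardGeneric("sireId"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("offspringIds", function(x) standardGeneric("offspringIds"))

#' @rdname GenotypeTable-class
#' @param sample,locus sample id and locus label to extract.
#' @export
setGeneric("alleleSet", function(x, sample, locus) standardGeneric("alleleSet"))

#' @rdname PrivateAlleleMatrix-class
#' @param x a \code{PrivateAlleleMatrix}.
#' @param parent \code{"DAM"} or \code{"SIRE"}.
#' @export
setGeneric("groupTotals", function(x, parent) standardGeneric("groupTotals"))

#' @rdname PrivateAlleleMatrix-class
#' @export
setGeneric("lociCounts", function(x, parent) standardGeneric("lociCounts"))

#' @rdname PrivateAlleleMatrix-class
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname GenotypeTable-class
setMethod("sampleInfo", "GenotypeTable", function(x) x@samples)

#' @rdname GenotypeTable-class
setMethod("genotypes", "GenotypeTable", function(x) x@genotypes)

#' @rdname GenotypeTable-class
setMethod("loci", "GenotypeTable", function(x) x@loci)

#' @rdname PrivateAlleleMatrix-class
setMethod("loci", "PrivateAlleleMatrix", function(x) x@loci)

#' @rdname GenotypeTable-class
setMethod("damId", "GenotypeTable",
          function(x) x@samples$sample_id[x@samples$role == "DAM"])

#' @rdname GenotypeTable-class
setMethod("sireId", "GenotypeTable",
          function(x) x@samples$sample_id[x@samples$role == "SIRE"])

#' @rdname GenotypeTable-class
setMethod("offspringIds", "GenotypeTable",
          function(x) x@samples$sample_id[x@samples$role == "OFFSPRING"])

#' @rdname GenotypeTable-class
setMethod("alleleSet", "GenotypeTable", function(x, sample, locus) {
  g <- x@genotypes
  sort(g$allele[g$sample_id == sample & g$locus == locus])
})

#' @rdname PrivateAlleleMatrix-class
setMethod("groupNames", "PrivateAlleleMatrix", function(x) names(x@groups))

#' @rdname PrivateAlleleMatrix-class
setMethod("groupTotals", "PrivateAlleleMatrix", function(x, parent) {
  cn <- x@counts[x@counts$parent == parent, , drop = FALSE]
  out <- setNames(numeric(length(x@groups)), names(x@groups))
  if (nrow(cn)) {
    agg <- tapply(cn$count, cn$group, sum)
    out[names(agg)] <- agg
  }
  out
})

#' @rdname PrivateAlleleMatrix-class
setMethod("lociCounts", "PrivateAlleleMatrix", function(x, parent) {
  cn <- x@counts[x@counts$parent == parent, , drop = FALSE]
  m <- matrix(0, nrow = length(x@loci), ncol = length(x@groups),
              dimnames = list(x@loci, names(x@groups)))
  if (nrow(cn)) m[cbind(cn$locus, cn$group)] <- cn$count
  m
})
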