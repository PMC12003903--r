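#' Accessors for signal2gene classes
#'
#' Small read-only accessors so downstream code never touches slots.
#'
#' @param x a signal2gene object.
#' @return `sumstatsData()` the record data.frame; `ancestry()` the ancestry
#'   label; `variantKeys()` the variant key data.frame; `dosages()` the
#'   dosage matrix; `sampleAncestry()` per-sample labels; `ldr()` the
#'   correlation matrix; `credibleMembers()` the member table; `csCenter()`
#'   the PIP-weighted center; `csLocus()` the locus GRanges;
#'   `prioritizationTable()` the candidate table.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sumstatsData", function(x) standardGeneric("sumstatsData"))
#' @rdname accessors
#' @export
setMethod("sumstatsData", "SumStats", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("ancestry", function(x) standardGeneric("ancestry"))
#' @rdname accessors
#' @export
setMethod("ancestry", "SumStats", function(x) x@ancestry)

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname accessors
#' @export
setMethod("variantKeys", "SumStats",
          function(x) x@data[, c("chrom", "pos", "a1", "a2")])
#' @rdname accessors
#' @export
setMethod("variantKeys", "GenotypePanel", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variantKeys", "LDMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)

#' @rdname accessors
#' @export
setGeneric("sampleAncestry", function(x) standardGeneric("sampleAncestry"))
#' @rdname accessors
#' @export
setMethod("sampleAncestry", "GenotypePanel", function(x) x@sampleAncestry)

#' @rdname accessors
#' @export
setGeneric("ldr", function(x) standardGeneric("ldr"))
#' @rdname accessors
#' @export
setMethod("ldr", "LDMatrix", function(x) x@r)

#' @rdname accessors
#' @export
setGeneric("abfTable", function(x) standardGeneric("abfTable"))
#' @rdname accessors
#' @export
setMethod("abfTable", "CredibleSet", function(x) x@abf)

#' @rdname accessors
#' @export
setGeneric("credibleMembers", function(x) standardGeneric("credibleMembers"))
#' @rdname accessors
#' @export
setMethod("credibleMembers", "CredibleSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("csCenter", function(x) standardGeneric("csCenter"))
#' @rdname accessors
#' @export
setMethod("csCenter", "CredibleSet", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("csLocus", function(x) standardGeneric("csLocus"))
#' @rdname accessors
#' @export
setMethod("csLocus", "CredibleSet", function(x) x@locus)

#' @rdname accessors
#' @export
setGeneric("prioritizationTable",
           function(x) standardGeneric("prioritizationTable"))
#' @rdname accessors
#' @export
setMethod("prioritizationTable", "PrioritizationResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("prioritizedLoci", function(x) standardGeneric("prioritizedLoci"))
#' @rdname accessors
#' @export
setMethod("prioritizedLoci", "PrioritizationResult", function(x) x@loci)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats: %d variants, ancestry %s\n",
              nrow(object@data), object@ancestry))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "GenotypePanel", function(object) {
  tab <- table(object@sampleAncestry)
  cat(sprintf("GenotypePanel: %d samples x %d variants (%s)\n",
              nrow(object@dosages), ncol(object@dosages),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d x %d\n", nrow(object@r), ncol(object@r)))
})

setMethod("show", "CredibleSet", function(object) {
  cat(sprintf(
    "CredibleSet %s: %d/%d variants, mass %.3f, center %s\n",
    object@signalId, nrow(object@members), nrow(object@abf), object@mass,
    format(object@center, big.mark = ",", scientific = FALSE)))
})

setMethod("show", "PrioritizationResult", function(object) {
  nsel <- sum(object@table$selected)
  cat(sprintf("PrioritizationResult: %d loci, %d candidate rows, %d selected genes\n",
              nrow(object@loci), nrow(object@table), nsel))
})
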