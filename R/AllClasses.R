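#' @import methods
#' @importFrom stats cor pchisq pnorm qnorm rnorm rchisq runif rbinom sd
#'   integrate setNames
#' @importFrom utils head tail
NULL

# required sumstats columns, in canonical order
.SUMSTATS_COLS <- c("chrom", "pos", "a1", "a2", "af", "beta", "se", "p",
                    "n_eff", "z")

.AUTOSOMES <- 1:22

#' Variant-level GWAS summary statistics
#'
#' Holds one study's (or one meta-analysis') variant-level association
#' records: bi-allelic autosomal SNVs with effect-allele frequency, effect
#' size on the log-odds scale, standard error, p-value and effective sample
#' size. Records are kept sorted by (chromosome, position, alleles) and
#' variant keys are unique.
#'
#' @slot data data.frame with columns chrom (integer, 1-22), pos (1-based
#'   integer), a1/a2 (effect/other allele, single bases), af (effect-allele
#'   frequency), beta, se, p, n_eff, z (= beta/se, cached).
#' @slot ancestry single ancestry label, e.g. "EUR".
#' @slot provenance free-text origin of the table.
#'
#' @export
setClass("SumStats",
  representation(data = "data.frame", ancestry = "character",
                 provenance = "character"),
  prototype(data = data.frame(), ancestry = NA_character_, provenance = ""))

setValidity("SumStats", function(object) {
  d <- object@data
  if (nrow(d) == 0L) return(TRUE)
  missing_cols <- setdiff(.SUMSTATS_COLS, names(d))
  if (length(missing_cols) > 0L)
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (!all(d$chrom %in% .AUTOSOMES)) return("chrom outside autosomes 1-22")
  if (any(d$pos < 1L)) return("pos must be >= 1")
  if (any(d$a1 == d$a2)) return("a1 == a2 for some records")
  if (any(d$se <= 0)) return("se must be > 0")
  if (any(d$af <= 0 | d$af >= 1)) return("af must be in (0,1)")
  if (any(abs(d$z * d$se - d$beta) > 1e-8 * pmax(1, abs(d$beta))))
    return("cached z inconsistent with beta/se")
  key <- variantId(d)
  if (anyDuplicated(key)) return("duplicate variant keys")
  o <- order(d$chrom, d$pos, d$a1, d$a2)
  if (!identical(o, seq_len(nrow(d)))) return("records not sorted")
  TRUE
})

#' Reference genotype panel
#'
#' Samples-by-variants dosage matrix (entries 0/1/2) with per-sample
#' ancestry labels, used as the LD reference for clumping, conditional
#' analysis, fine-mapping simulation and the gene-test null.
#'
#' @slot dosages numeric matrix, rows samples, columns variants.
#' @slot variants data.frame with chrom, pos, a1, a2 (column order matches
#'   the dosage columns).
#' @slot sampleAncestry character vector, one label per sample.
#' @slot sampleIds character vector of sample identifiers.
#'
#' @export
setClass("GenotypePanel",
  representation(dosages = "matrix", variants = "data.frame",
                 sampleAncestry = "character", sampleIds = "character"))

setValidity("GenotypePanel", function(object) {
  d <- object@dosages
  v <- object@variants
  if (ncol(d) != nrow(v)) return("dosage columns != variant rows")
  if (nrow(d) != length(object@sampleAncestry))
    return("sampleAncestry length != sample count")
  if (nrow(d) != length(object@sampleIds))
    return("sampleIds length != sample count")
  if (nrow(v) > 0L && !all(c("chrom", "pos", "a1", "a2") %in% names(v)))
    return("variants needs chrom/pos/a1/a2")
  if (length(d) > 0L && !all(d %in% 0:2)) return("dosages must be 0/1/2")
  TRUE
})

#' Signed LD correlation matrix
#'
#' Pearson correlation r between dosage columns of a reference panel,
#' restricted to an ordered variant subset. The matrix is symmetrized and,
#' on request, stabilized to be positive semi-definite so Cholesky
#' factorizations downstream cannot fail.
#'
#' @slot r numeric correlation matrix, unit diagonal.
#' @slot variants data.frame of the variant keys, in column order.
#'
#' @export
setClass("LDMatrix",
  representation(r = "matrix", variants = "data.frame"))

setValidity("LDMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("r not square")
  if (nrow(r) != nrow(object@variants)) return("variants length != dim(r)")
  if (nrow(r) > 0L) {
    if (max(abs(r - t(r))) > 1e-12) return("r not symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) return("diagonal not 1")
    if (max(abs(r)) > 1 + 1e-8) return("|r| > 1")
  }
  TRUE
})

#' Fine-mapped credible set for one isolated signal
#'
#' Result of single-causal-variant fine-mapping: the per-variant log
#' approximate Bayes factors and posterior inclusion probabilities (PIPs),
#' the minimal descending-PIP 95 percent credible set, its PIP-weighted
#' center, and the derived locus interval.
#'
#' @slot signalId identifier of the isolated signal.
#' @slot abf data.frame with chrom, pos, a1, a2, z, labf, pip, inCS for
#'   every fine-mapped variant.
#' @slot members data.frame of credible-set members ordered by descending
#'   PIP (ties by position).
#' @slot mass cumulative PIP of the members (>= target mass).
#' @slot center PIP-weighted average member position, rounded to base pair.
#' @slot locus GRanges of length 1: credible-set span padded both sides.
#'
#' @export
setClass("CredibleSet",
  representation(signalId = "character", abf = "data.frame",
                 members = "data.frame", mass = "numeric",
                 center = "numeric", locus = "ANY"))

setValidity("CredibleSet", function(object) {
  a <- object@abf
  if (nrow(a) > 0L) {
    if (abs(sum(a$pip) - 1) > 1e-10) return("pips do not sum to 1")
    if (nrow(object@members) < 1L) return("empty credible set")
    sp <- range(object@members$pos)
    if (object@center < sp[1] - 0.5 || object@center > sp[2] + 0.5)
      return("center outside member span")
  }
  TRUE
})

#' Per-locus gene prioritization result
#'
#' One row per candidate gene per locus with distance to the credible-set
#' center, feature-score percentile, gene association z, non-synonymous
#' credible-set PIP, criteria flags, and the locus-level selection.
#'
#' @slot table data.frame with columns signal_id, gene_id, distance_kb,
#'   pops_percentile, gene_z, nonsyn_pip, n_genes_in_locus, flag_top_pops,
#'   flag_nearest, flag_nonsyn, selected.
#' @slot loci data.frame of per-locus summaries (signal_id, chrom, start,
#'   end, center, n_genes, selected_gene).
#'
#' @export
setClass("PrioritizationResult",
  representation(table = "data.frame", loci = "data.frame"))

setValidity("PrioritizationResult", function(object) {
  t <- object@table
  if (nrow(t) > 0L) {
    nsel <- tapply(t$selected, t$signal_id, sum)
    if (any(nsel > 1L)) return("more than one selected gene in a locus")
  }
  TRUE
})
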