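#' Read a non-synonymous variant list
#'
#' TSV with columns CHR, BP, A1, A2 flagging coding variants that change
#' the protein sequence.
#'
#' @param path path to the TSV.
#' @return data.frame(chrom, pos, a1, a2).
#' @export
readNonsynVariants <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  data.frame(chrom = as.integer(d$CHR), pos = as.integer(d$BP),
             a1 = as.character(d$A1), a2 = as.character(d$A2))
}

#' Genes overlapping a locus
#'
#' Closed-interval overlap between gene bodies and the locus; a gene
#' exactly abutting the locus boundary is included.
#'
#' @param locus GRanges of length 1.
#' @param genes GRanges gene models.
#' @return list(genes = GRanges subset, count = number of genes).
#' @export
genesInLocus <- function(locus, genes) {
  hits <- GenomicRanges::findOverlaps(genes, locus, ignore.strand = TRUE)
  g <- genes[S4Vectors::queryHits(hits)]
  list(genes = g, count = length(g))
}

#' Distance from a gene body to the credible-set center
#'
#' 0 kb when the center lies inside the gene body (start <= center <=
#' end), otherwise the distance to the nearest gene edge, in kb.
#'
#' @param start,end gene body interval (1-based inclusive), vectorized.
#' @param center credible-set PIP-weighted center position.
#' @param geneChrom,centerChrom optional chromosomes; supplying both on
#'   different chromosomes is an error.
#' @return distance in kb (numeric).
#' @export
geneCsDistance <- function(start, end, center, geneChrom = NULL,
                           centerChrom = NULL) {
  if (!is.null(geneChrom) && !is.null(centerChrom) &&
      any(geneChrom != centerChrom))
    stop("gene and credible-set center on different chromosomes")
  inside <- start <= center & center <= end
  ifelse(inside, 0, pmin(abs(center - start), abs(center - end)) / 1000)
}

#' Apply the per-locus gene selection rule
#'
#' Rule A: the gene with the top feature score is selected if it is also
#' the nearest gene to the credible-set center (ties in either argmax or
#' argmin void rule A). Rule B: any gene whose summed PIP of
#' non-synonymous credible-set variants exceeds `nonsynThreshold`. When
#' both fire, rule B wins (the non-synonymous gene is the selection).
#'
#' @param candidates data.frame with gene_id, distance_kb, pops (raw
#'   score used for the argmax; NA excluded), nonsyn_pip.
#' @param nonsynThreshold strict threshold on the summed non-synonymous
#'   PIP.
#' @return list(selected = gene id or NA, flags = data.frame(gene_id,
#'   flag_top_pops, flag_nearest, flag_nonsyn)).
#' @export
prioritizeLocus <- function(candidates, nonsynThreshold = 0.5) {
  stopifnot(nrow(candidates) > 0L)
  pops <- candidates$pops
  top <- rep(FALSE, nrow(candidates))
  if (any(!is.na(pops))) {
    mx <- max(pops, na.rm = TRUE)
    top <- !is.na(pops) & pops == mx
  }
  near <- candidates$distance_kb == min(candidates$distance_kb)
  nonsyn <- candidates$nonsyn_pip > nonsynThreshold

  ruleA <- NA_character_
  if (sum(top) == 1L && sum(near) == 1L && which(top) == which(near))
    ruleA <- candidates$gene_id[top]
  ruleB <- candidates$gene_id[nonsyn]
  selected <- if (length(ruleB) >= 1L) ruleB[1] else ruleA
  list(selected = selected,
       flags = data.frame(gene_id = candidates$gene_id,
                          flag_top_pops = top, flag_nearest = near,
                          flag_nonsyn = nonsyn))
}

#' Prioritize genes across all fine-mapped loci
#'
#' For every credible set: finds the genes overlapping its locus, computes
#' each gene's distance to the PIP-weighted center, attaches feature-score
#' and gene-association values, sums the PIPs of non-synonymous
#' credible-set variants falling inside each gene body, and applies
#' [prioritizeLocus()]. Genes harbouring above-threshold non-synonymous
#' credible-set PIP but lying outside the locus interval are added as
#' candidates with a warning.
#'
#' @param credibleSets list of [CredibleSet-class] objects.
#' @param genes GRanges gene models.
#' @param pops [popsScore()] output (gene_id, pops_meta,
#'   pops_percentile).
#' @param geneScores [metaGeneZ()] output (gene_id, z_meta).
#' @param nonsyn data.frame of non-synonymous variants (chrom, pos, a1,
#'   a2), or NULL for none.
#' @param nonsynThreshold strict PIP threshold for rule B.
#' @return a [PrioritizationResult-class].
#' @export
prioritizeGenes <- function(credibleSets, genes, pops, geneScores,
                            nonsyn = NULL, nonsynThreshold = 0.5) {
  nonsyn_ids <- if (is.null(nonsyn)) character(0) else variantId(nonsyn)
  rows <- list()
  loci <- list()
  for (cs in credibleSets) {
    locus <- csLocus(cs)
    gl <- genesInLocus(locus, genes)
    cand <- gl$genes
    n_in_locus <- gl$count

    # summed PIP of non-synonymous credible-set variants per gene body
    mem <- credibleMembers(cs)
    ns_pip <- setNames(numeric(0), character(0))
    ns_mem <- mem[variantId(mem) %in% nonsyn_ids, , drop = FALSE]
    if (nrow(ns_mem) > 0L) {
      vgr <- GenomicRanges::GRanges(
        seqnames = as.character(ns_mem$chrom),
        ranges = IRanges::IRanges(start = ns_mem$pos, width = 1L))
      ov <- GenomicRanges::findOverlaps(vgr, genes, ignore.strand = TRUE)
      if (length(ov) > 0L) {
        gid <- S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(ov)]
        ns_pip <- tapply(ns_mem$pip[S4Vectors::queryHits(ov)], gid, sum)
      }
    }
    extra <- setdiff(names(ns_pip)[ns_pip > nonsynThreshold],
                     S4Vectors::mcols(cand)$gene_id)
    if (length(extra) > 0L) {
      warning("signal ", cs@signalId, ": non-synonymous gene(s) outside ",
              "the locus interval added as candidate(s): ",
              paste(extra, collapse = ", "))
      cand <- c(cand, genes[S4Vectors::mcols(genes)$gene_id %in% extra])
    }
    if (length(cand) == 0L) {
      loci[[length(loci) + 1L]] <- data.frame(
        signal_id = cs@signalId,
        chrom = as.integer(as.character(
          GenomicRanges::seqnames(locus))),
        start = GenomicRanges::start(locus),
        end = GenomicRanges::end(locus), center = csCenter(cs),
        n_genes = 0L, selected_gene = NA_character_)
      next
    }
    cdf <- data.frame(
      gene_id = S4Vectors::mcols(cand)$gene_id,
      distance_kb = geneCsDistance(GenomicRanges::start(cand),
                                   GenomicRanges::end(cand),
                                   csCenter(cs)),
      stringsAsFactors = FALSE)
    cdf$pops <- pops$pops_meta[match(cdf$gene_id, pops$gene_id)]
    cdf$pops_percentile <-
      pops$pops_percentile[match(cdf$gene_id, pops$gene_id)]
    cdf$gene_z <- geneScores$z_meta[match(cdf$gene_id,
                                          geneScores$gene_id)]
    cdf$nonsyn_pip <- ifelse(cdf$gene_id %in% names(ns_pip),
                             ns_pip[cdf$gene_id], 0)
    sel <- prioritizeLocus(cdf, nonsynThreshold)
    rows[[length(rows) + 1L]] <- data.frame(
      signal_id = cs@signalId, cdf[, c("gene_id", "distance_kb",
                                       "pops_percentile", "gene_z",
                                       "nonsyn_pip")],
      n_genes_in_locus = n_in_locus,
      sel$flags[, c("flag_top_pops", "flag_nearest", "flag_nonsyn")],
      selected = !is.na(sel$selected) & cdf$gene_id == sel$selected)
    loci[[length(loci) + 1L]] <- data.frame(
      signal_id = cs@signalId,
      chrom = as.integer(as.character(GenomicRanges::seqnames(locus))),
      start = GenomicRanges::start(locus),
      end = GenomicRanges::end(locus), center = csCenter(cs),
      n_genes = n_in_locus,
      selected_gene = if (is.na(sel$selected)) NA_character_ else
        sel$selected)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(signal_id = character(0), gene_id = character(0),
               distance_kb = numeric(0), pops_percentile = numeric(0),
               gene_z = numeric(0), nonsyn_pip = numeric(0),
               n_genes_in_locus = integer(0),
               flag_top_pops = logical(0), flag_nearest = logical(0),
               flag_nonsyn = logical(0), selected = logical(0))
  rownames(table) <- NULL
  ldf <- if (length(loci)) do.call(rbind, loci) else
    data.frame(signal_id = character(0), chrom = integer(0),
               start = numeric(0), end = numeric(0), center = numeric(0),
               n_genes = integer(0), selected_gene = character(0))
  rownames(ldf) <- NULL
  new("PrioritizationResult", table = table, loci = ldf)
}

#' Write the final prioritization table
#'
#' One row per candidate gene per locus, mirroring the heatmap columns:
#' gene, signal, distance, feature-score percentile, gene z, gene count
#' and criteria flags.
#'
#' @param result a [PrioritizationResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePrioritization <- function(result, path) {
  t <- prioritizationTable(result)
  out <- data.frame(GENE = t$gene_id, SIGNAL_ID = t$signal_id,
                    DISTANCE_KB = t$distance_kb,
                    POPS_PERCENTILE = t$pops_percentile,
                    MAGMA_Z = t$gene_z,
                    N_GENES_IN_LOCUS = t$n_genes_in_locus,
                    FLAG_TOP_POPS = t$flag_top_pops,
                    FLAG_NEAREST = t$flag_nearest,
                    FLAG_NONSYN = t$flag_nonsyn,
                    SELECTED = t$selected)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
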