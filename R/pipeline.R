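#' Export regions or loci as BED-like TSV
#'
#' Internal 1-based closed intervals are converted to 0-based half-open
#' BED coordinates (START0 = start - 1, END unchanged).
#'
#' @param d data.frame with chrom, start, end (plus extra columns kept).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedTSV <- function(d, path) {
  out <- data.frame(CHR = d$chrom, START = d$start - 1, END = d$end)
  extra <- setdiff(names(d), c("chrom", "start", "end", "clumpIdx"))
  for (col in extra) out[[toupper(col)]] <- d[[col]]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a BED-like TSV back to 1-based closed intervals
#'
#' @param path path written by [writeBedTSV()].
#' @return data.frame with chrom, start, end (1-based closed).
#' @export
readBedTSV <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  out <- data.frame(chrom = d$CHR, start = d$START + 1, end = d$END)
  for (col in setdiff(names(d), c("CHR", "START", "END")))
    out[[tolower(col)]] <- d[[col]]
  out
}

#' Run the full prioritization pipeline on a fixture bundle
#'
#' Executes, in order: per-ancestry harmonization to the ancestry panel
#' and allele-frequency QC; variant-level fixed-effects meta-analysis;
#' ancestry-mixed panel construction in GWAS proportions; clumping,
#' region construction, stepwise selection and leave-one-hit-out signal
#' isolation; per-signal fine-mapping into credible sets and loci;
#' per-ancestry MAF filtering and gene-level association with sqrt(N)
#' meta-analysis; feature-based gene scoring; and the per-locus
#' prioritization rule. Fully deterministic given the fixture and
#' `seed`.
#'
#' @param fx a [makeFixture()] bundle, or a named list with the same
#'   elements read from files (panels, sumstats, genes, features, nonsyn).
#' @param outDir optional directory; when given every stage's output is
#'   written as TSV.
#' @param seed seed for the panel-mixing subsample.
#' @param pThresh genome-wide significance threshold.
#' @param r2Thresh,windowBp,padBp clumping/region parameters.
#' @param r2Collinear collinearity cutoff in conditional analysis.
#' @param priorSd fine-mapping prior effect-size sd.
#' @param csMass credible-set mass.
#' @param locusPadBp locus padding around the credible-set span.
#' @param mafMin gene-analysis minor-allele-frequency cutoff.
#' @param minVariants minimum variants per gene.
#' @param nullMethod gene-test null approximation, see
#'   [weightedChisqSF()].
#' @param alpha marginal feature-selection threshold.
#' @param penalty ridge penalty or "gcv".
#' @param nonsynThreshold non-synonymous PIP threshold.
#' @return list with qc (per-ancestry removal counts), meta (SumStats),
#'   mixedPanel, signals (from [findIndependentSignals()]), credibleSets,
#'   geneScores (per ancestry), geneMeta, pops, result
#'   ([PrioritizationResult-class]).
#' @export
runPipeline <- function(fx, outDir = NULL, seed = 1L, pThresh = 5e-8,
                        r2Thresh = 0.1, windowBp = 3e6, padBp = 5e5,
                        r2Collinear = 0.9, priorSd = 0.2, csMass = 0.95,
                        locusPadBp = 3e5, mafMin = 0.01,
                        minVariants = 3L,
                        nullMethod = "satterthwaite", alpha = 0.05,
                        penalty = 100, nonsynThreshold = 0.5) {
  anc <- names(fx$sumstats)
  nEff <- vapply(fx$sumstats, function(s)
    max(sumstatsData(s)$n_eff), numeric(1))

  # stage 1: harmonize + AF QC per ancestry
  qc <- list(); clean <- list()
  for (a in anc) {
    h <- harmonizeToPanel(fx$sumstats[[a]], fx$panels[[a]])
    q <- qcAlleleFrequency(h$sumstats, panelAlleleFreq(fx$panels[[a]]))
    qc[[a]] <- c(h$counts, q$counts)
    clean[[a]] <- q$sumstats
  }

  # stage 2: variant-level fixed-effects meta-analysis
  meta <- metaAnalyze(clean, scheme = "ivw")

  # stage 3: ancestry-mixed LD panel in GWAS proportions
  mixed <- buildMixedPanel(fx$panels, nEff / sum(nEff), seed = seed)

  # stage 4: independent signals
  sig <- findIndependentSignals(meta, mixed$panel, pThresh = pThresh,
                                r2Thresh = r2Thresh, windowBp = windowBp,
                                padBp = padBp,
                                r2Collinear = r2Collinear)

  # stage 5: fine-mapping
  credibleSets <- lapply(sig$signals, fineMapSignal, priorSd = priorSd,
                         mass = csMass, padBp = locusPadBp)

  # stage 6: gene-level association per ancestry + sqrt(N) meta
  geneScores <- list()
  for (a in anc) {
    geneScores[[a]] <- geneAssociation(mafFilter(clean[[a]], mafMin),
                                       fx$panels[[a]], fx$genes,
                                       minVariants = minVariants,
                                       method = nullMethod)
  }
  geneMeta <- metaGeneZ(geneScores, nEff)

  # stage 7: feature-based scoring
  pops <- popsScore(geneScores, fx$features, nEff, alpha = alpha,
                    penalty = penalty)

  # stage 8: prioritization
  result <- prioritizeGenes(credibleSets, fx$genes, pops, geneMeta,
                            nonsyn = fx$nonsyn,
                            nonsynThreshold = nonsynThreshold)

  out <- list(qc = qc, meta = meta, mixedPanel = mixed,
              signals = sig, credibleSets = credibleSets,
              geneScores = geneScores, geneMeta = geneMeta, pops = pops,
              result = result)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

#' Write every pipeline stage's output as TSV
#'
#' @param out a [runPipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePipelineOutputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSumstats(out$meta, file.path(dir, "meta_sumstats.tsv"))
  qc <- do.call(rbind, lapply(names(out$qc), function(a)
    data.frame(ANCESTRY = a, RULE = names(out$qc[[a]]),
               N = as.integer(out$qc[[a]]))))
  data.table::fwrite(qc, file.path(dir, "qc_counts.tsv"), sep = "\t")
  if (nrow(out$signals$regions) > 0L)
    writeBedTSV(out$signals$regions, file.path(dir, "regions.tsv"))
  if (!is.null(out$signals$hits))
    data.table::fwrite(out$signals$hits[,
      c("chrom", "pos", "a1", "a2", "joint_z", "joint_p", "region")],
      file.path(dir, "hits.tsv"), sep = "\t")
  if (length(out$signals$signals) > 0L) {
    cond <- do.call(rbind, lapply(out$signals$signals, function(s) {
      data.frame(SIGNAL_ID = s$signal_id, CHR = s$chrom, BP = s$pos,
                 A1 = s$a1, A2 = s$a2, FREQ = s$af, BETA = s$beta,
                 SE = s$se, P = s$p, N_EFF = s$n_eff)
    }))
    data.table::fwrite(cond, file.path(dir, "conditioned_sumstats.tsv"),
                       sep = "\t")
  }
  if (length(out$credibleSets) > 0L) {
    abf <- do.call(rbind, lapply(out$credibleSets, function(cs) {
      a <- abfTable(cs)
      data.frame(SIGNAL_ID = cs@signalId, CHR = a$chrom, BP = a$pos,
                 A1 = a$a1, A2 = a$a2, Z = a$z, LABF = a$labf,
                 PIP = a$pip, IN_CS = a$inCS)
    }))
    data.table::fwrite(abf, file.path(dir, "finemap_abf.tsv"),
                       sep = "\t")
    loci <- do.call(rbind, lapply(out$credibleSets, function(cs) {
      l <- csLocus(cs)
      data.frame(chrom =
                   as.integer(as.character(GenomicRanges::seqnames(l))),
                 start = GenomicRanges::start(l),
                 end = GenomicRanges::end(l),
                 signal_id = cs@signalId, center = csCenter(cs))
    }))
    writeBedTSV(loci, file.path(dir, "loci.tsv"))
  }
  gm <- out$geneMeta
  for (a in names(out$geneScores)) {
    s <- out$geneScores[[a]]
    gm[[paste0("n_variants_", a)]] <-
      s$n_variants[match(gm$gene_id, s$gene_id)]
    gm[[paste0("p_", a)]] <- s$p[match(gm$gene_id, s$gene_id)]
  }
  data.table::fwrite(gm, file.path(dir, "gene_scores.tsv"), sep = "\t")
  data.table::fwrite(out$pops, file.path(dir, "pops_scores.tsv"),
                     sep = "\t")
  writePrioritization(out$result, file.path(dir, "prioritization.tsv"))
  invisible(dir)
}
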