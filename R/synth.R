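#' Specification for a synthetic GWAS fixture
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate a two-ancestry (EUR-majority, EAS-minority) case-control GWAS
#' at desk scale: block-LD reference panels, planted causal genes with
#' genome-wide-significant signals, pathway-structured gene features
#' enriched in causal genes, and non-synonymous annotations. Effective
#' sample sizes default to the study sizes of a large two-ancestry
#' Parkinson's disease meta-analysis (127,626 EUR, 15,886 EAS).
#'
#' @param nSamples named per-ancestry reference-panel sample counts.
#' @param nEff named per-ancestry GWAS effective sample sizes.
#' @param nBlocks number of LD blocks (one candidate locus each).
#' @param variantsPerBlock variants per block.
#' @param variantSpacing base pairs between adjacent variants.
#' @param rho named per-ancestry AR(1) within-block LD correlation.
#' @param mafRange minor-allele-frequency bounds (uniform draw).
#' @param genesPerBlock genes tiled across each block.
#' @param geneLength gene body length in bp.
#' @param geneSpacing gap between adjacent genes in bp.
#' @param nChrom chromosomes the blocks are spread over (<= 22).
#' @param blockSpacing bp between block starts on the same chromosome
#'   (large enough that padded regions never merge).
#' @param effectZ expected meta-analysis z at each causal variant
#'   (per-SD effect b = effectZ / sqrt(sum(nEff))).
#' @param causalGeneIndex which gene of each block carries the causal
#'   variant.
#' @param nHard number of "hard" blocks: the causal variant is flagged
#'   non-synonymous while the pathway features point at a neighbouring
#'   gene, so selection must come from the non-synonymous rule.
#' @param nTrueFeatures number of causal-gene-enriched binary pathway
#'   features.
#' @param enrichmentExtra random non-causal genes added to each true
#'   pathway.
#' @param nNoiseFeatures independent standard-normal noise features.
#' @param nonsynFraction background fraction of variants flagged
#'   non-synonymous (on top of hard-block causal variants).
#' @param seed master seed; every stochastic step derives its own stream
#'   from it.
#' @return a list of class "fixtureSpec".
#' @export
fixtureSpec <- function(nSamples = c(EUR = 400L, EAS = 200L),
                        nEff = c(EUR = 127626, EAS = 15886),
                        nBlocks = 20L, variantsPerBlock = 88L,
                        variantSpacing = 5000L,
                        rho = c(EUR = 0.9, EAS = 0.8),
                        mafRange = c(0.05, 0.5),
                        genesPerBlock = 4L, geneLength = 1e5L,
                        geneSpacing = 1e4L, nChrom = 10L,
                        blockSpacing = 2e7, effectZ = 10,
                        causalGeneIndex = 2L, nHard = 4L,
                        nTrueFeatures = 5L, enrichmentExtra = 5L,
                        nNoiseFeatures = 500L, nonsynFraction = 0.02,
                        seed = 1L) {
  spec <- list(nSamples = nSamples, nEff = nEff, nBlocks = nBlocks,
               variantsPerBlock = variantsPerBlock,
               variantSpacing = variantSpacing, rho = rho,
               mafRange = mafRange, genesPerBlock = genesPerBlock,
               geneLength = geneLength, geneSpacing = geneSpacing,
               nChrom = nChrom, blockSpacing = blockSpacing,
               effectZ = effectZ, causalGeneIndex = causalGeneIndex,
               nHard = nHard, nTrueFeatures = nTrueFeatures,
               enrichmentExtra = enrichmentExtra,
               nNoiseFeatures = nNoiseFeatures,
               nonsynFraction = nonsynFraction, seed = seed)
  stopifnot(all(unlist(spec[c("nBlocks", "variantsPerBlock",
                              "genesPerBlock", "nChrom")]) > 0),
            all(rho >= 0), all(rho < 1),
            identical(sort(names(nSamples)), sort(names(nEff))),
            identical(sort(names(nSamples)), sort(names(rho))),
            spec$nChrom <= 22L, spec$nHard <= spec$nBlocks,
            spec$causalGeneIndex <= spec$genesPerBlock)
  class(spec) <- "fixtureSpec"
  spec
}

# AR(1) correlation matrix
.ar1 <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

#' Deterministic genomic layout of a fixture
#'
#' Places blocks on chromosomes, tiles genes over each block, draws
#' per-variant MAFs, and designates the causal variant (the variant
#' closest to the causal gene's midpoint) and the hard blocks (the last
#' `nHard` blocks).
#'
#' @param spec a [fixtureSpec()].
#' @return list(variants = data.frame(chrom, pos, a1, a2, maf, block),
#'   genes = GRanges, truth = per-block data.frame with the causal
#'   variant, causal gene, featured gene and expected rule).
#' @export
fixtureLayout <- function(spec) {
  set.seed(.deriveSeed(spec$seed, 1L))
  vlist <- list(); glist <- list(); tlist <- list()
  for (b in seq_len(spec$nBlocks)) {
    chrom <- (b - 1L) %% spec$nChrom + 1L
    slot <- (b - 1L) %/% spec$nChrom
    base <- 1e6 + slot * spec$blockSpacing
    pos <- base + (seq_len(spec$variantsPerBlock) - 1L) *
      spec$variantSpacing
    maf <- runif(spec$variantsPerBlock, spec$mafRange[1],
                 spec$mafRange[2])
    vlist[[b]] <- data.frame(chrom = chrom, pos = as.integer(pos),
                             a1 = "A", a2 = "G", maf = maf, block = b)
    gstart <- base + (seq_len(spec$genesPerBlock) - 1L) *
      (spec$geneLength + spec$geneSpacing)
    gid <- sprintf("GENE_B%02d_%d", b, seq_len(spec$genesPerBlock))
    glist[[b]] <- data.frame(gene_id = gid, chrom = chrom,
                             start = as.integer(gstart),
                             end = as.integer(gstart + spec$geneLength -
                                                1L),
                             strand = rep(c("+", "-"),
                                          length.out =
                                            spec$genesPerBlock),
                             block = b)
    ci <- spec$causalGeneIndex
    mid <- gstart[ci] + spec$geneLength / 2
    cv <- which.min(abs(pos - mid))
    hard <- b > spec$nBlocks - spec$nHard
    featured_idx <- if (hard) min(ci + 1L, spec$genesPerBlock) else ci
    tlist[[b]] <- data.frame(
      block = b, chrom = chrom, causal_variant = cv,
      causal_pos = as.integer(pos[cv]), causal_gene = gid[ci],
      featured_gene = gid[featured_idx], hard = hard,
      expected_rule = if (hard) "B" else "A", expected_gene = gid[ci])
  }
  variants <- do.call(rbind, vlist)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, ]
  rownames(variants) <- NULL
  gdf <- do.call(rbind, glist)
  genes <- makeGeneModels(gdf)
  S4Vectors::mcols(genes)$block <-
    gdf$block[match(S4Vectors::mcols(genes)$gene_id, gdf$gene_id)]
  list(variants = variants, genes = genes, truth = do.call(rbind, tlist))
}

#' Simulate a block-LD genotype reference panel
#'
#' Haplotypes follow a Gaussian copula: a latent AR(1) normal vector per
#' block is thresholded at the (1 - MAF) quantile, so each haplotype
#' carries the effect allele with probability MAF and adjacent variants
#' are correlated; a genotype is the sum of two independent haplotypes.
#'
#' @param spec a [fixtureSpec()].
#' @param layout a [fixtureLayout()] (defaults to the spec's layout).
#' @param ancestry which ancestry's sample size and rho to use.
#' @param seed seed (defaults to a stream derived from the spec seed).
#' @return a [GenotypePanel-class].
#' @export
simulatePanel <- function(spec, layout = fixtureLayout(spec),
                          ancestry = names(spec$nSamples)[1],
                          seed = NULL) {
  n <- spec$nSamples[[ancestry]]
  rho <- spec$rho[[ancestry]]
  if (is.null(seed))
    seed <- .deriveSeed(spec$seed, 100L + match(ancestry,
                                                names(spec$nSamples)))
  set.seed(seed)
  v <- layout$variants
  dos <- matrix(0, nrow = n, ncol = nrow(v))
  for (b in unique(v$block)) {
    idx <- which(v$block == b)
    m <- length(idx)
    L <- chol(.ar1(m, rho))
    thr <- qnorm(1 - v$maf[idx])
    hap <- function() {
      z <- matrix(rnorm(n * m), n, m) %*% L
      t(t(z) > thr) + 0
    }
    dos[, idx] <- hap() + hap()
  }
  makeGenotypePanel(dos, v[, c("chrom", "pos", "a1", "a2")],
                    rep(ancestry, n),
                    sprintf("%s%04d", ancestry, seq_len(n)))
}

#' Simulate GWAS summary statistics from an LD matrix
#'
#' Standard summary-statistic likelihood: z = sqrt(N) R b + L eps with L
#' the Cholesky factor of R and eps standard normal. Per-allele scale:
#' se = 1 / sqrt(2 f (1 - f) N), beta = z * se, p two-sided normal.
#'
#' @param R [LDMatrix-class] or PSD correlation matrix.
#' @param b per-SD true effect vector aligned with `R`.
#' @param nEff effective sample size.
#' @param mafs effect-allele frequencies aligned with `R`.
#' @param seed integer seed.
#' @param keys data.frame(chrom, pos, a1, a2); defaults to the LDMatrix's
#'   variants.
#' @param ancestry label for the returned table.
#' @return a [SumStats-class].
#' @export
simulateSumstats <- function(R, b, nEff, mafs, seed = 1L, keys = NULL,
                             ancestry = NA_character_) {
  if (is(R, "LDMatrix")) {
    if (is.null(keys)) keys <- variantKeys(R)
    R <- ldr(R)
  }
  m <- nrow(R)
  if (length(b) != m || length(mafs) != m)
    stop("b/mafs length does not match R")
  if (is.null(keys)) stop("keys required when R is a plain matrix")
  set.seed(seed)
  L <- chol(.psdStabilize(R)$r)
  z <- sqrt(nEff) * as.numeric(R %*% b) +
    as.numeric(crossprod(L, rnorm(m)))
  se <- 1 / sqrt(2 * mafs * (1 - mafs) * nEff)
  d <- data.frame(keys, af = mafs, beta = z * se, se = se,
                  p = .pFromZ(z), n_eff = nEff)
  makeSumStats(d, ancestry = ancestry, provenance = "simulated")
}

#' Simulate a pathway-structured gene-by-feature matrix
#'
#' Builds `nTrueFeatures` binary pathway features each containing every
#' featured (causal-pathway) gene plus `enrichmentExtra` random other
#' genes, and `nNoiseFeatures` independent standard-normal features.
#'
#' @param geneIds all gene identifiers (matrix rows).
#' @param featuredGeneIds genes every true pathway contains.
#' @param spec a [fixtureSpec()] (uses nTrueFeatures, enrichmentExtra,
#'   nNoiseFeatures).
#' @param seed integer seed.
#' @return numeric matrix, rownames `geneIds`; true pathways are named
#'   PATHWAY_1.. and noise features NOISE_1.. .
#' @export
simulateGeneFeatures <- function(geneIds, featuredGeneIds, spec,
                                 seed = NULL) {
  if (is.null(seed)) seed <- .deriveSeed(spec$seed, 7L)
  set.seed(seed)
  G <- length(geneIds)
  ntrue <- spec$nTrueFeatures
  X <- matrix(0, nrow = G, ncol = ntrue + spec$nNoiseFeatures,
              dimnames = list(geneIds,
                              c(sprintf("PATHWAY_%d", seq_len(ntrue)),
                                sprintf("NOISE_%d",
                                        seq_len(spec$nNoiseFeatures)))))
  others <- setdiff(geneIds, featuredGeneIds)
  for (j in seq_len(ntrue)) {
    extra <- sample(others, min(spec$enrichmentExtra, length(others)))
    X[c(featuredGeneIds, extra), j] <- 1
  }
  X[, ntrue + seq_len(spec$nNoiseFeatures)] <-
    rnorm(G * spec$nNoiseFeatures)
  X
}

#' Build a complete synthetic input bundle with known ground truth
#'
#' Generates per-ancestry reference panels, per-ancestry summary
#' statistics with planted causal variants (per-ancestry LD taken from
#' the ancestry's own panel), gene models, a pathway-enriched feature
#' matrix, and a non-synonymous variant list. Clean blocks satisfy the
#' top-score-and-nearest rule by construction; hard blocks point the
#' pathway features at a neighbouring gene and flag the causal variant
#' non-synonymous, so only the non-synonymous rule recovers the truth.
#'
#' @param spec a [fixtureSpec()].
#' @param dir optional directory: when given, every input is also written
#'   in its external file format (sumstats TSV, dosage TSV, gene TSV,
#'   feature TSV, nonsyn TSV, truth_table.tsv, fixture_manifest.json).
#' @return list(spec, layout, panels (named list), sumstats (named list),
#'   genes, features, nonsyn, truth).
#' @export
makeFixture <- function(spec = fixtureSpec(), dir = NULL) {
  if (spec$nBlocks < 1L) stop("infeasible spec: no blocks")
  layout <- fixtureLayout(spec)
  anc <- names(spec$nSamples)
  panels <- lapply(anc, function(a) simulatePanel(spec, layout, a))
  names(panels) <- anc

  v <- layout$variants
  b_all <- rep(0, nrow(v))
  for (i in seq_len(nrow(layout$truth))) {
    blk <- layout$truth$block[i]
    idx <- which(v$block == blk)
    b_all[idx[layout$truth$causal_variant[i]]] <-
      spec$effectZ / sqrt(sum(spec$nEff))
  }

  sumstats <- list()
  for (a in anc) {
    zparts <- list()
    set.seed(.deriveSeed(spec$seed, 200L + match(a, anc)))
    seeds <- sample.int(2^30, spec$nBlocks)
    dl <- list()
    for (blk in sort(unique(v$block))) {
      idx <- which(v$block == blk)
      R <- ldCorrelation(panels[[a]],
                         v[idx, c("chrom", "pos", "a1", "a2")])
      ss <- simulateSumstats(R, b_all[idx], spec$nEff[[a]], v$maf[idx],
                             seed = seeds[blk], ancestry = a)
      dl[[length(dl) + 1L]] <- sumstatsData(ss)
    }
    sumstats[[a]] <- makeSumStats(do.call(rbind, dl), ancestry = a,
                                  provenance = "synthetic fixture")
  }

  featured <- unique(layout$truth$featured_gene)
  features <- simulateGeneFeatures(
    S4Vectors::mcols(layout$genes)$gene_id, featured, spec)

  # non-synonymous list: hard-block causal variants plus random background
  set.seed(.deriveSeed(spec$seed, 9L))
  bg <- which(runif(nrow(v)) < spec$nonsynFraction)
  hard_idx <- vapply(which(layout$truth$hard), function(i) {
    idx <- which(v$block == layout$truth$block[i])
    idx[layout$truth$causal_variant[i]]
  }, integer(1))
  ns_idx <- sort(unique(c(bg, hard_idx)))
  nonsyn <- v[ns_idx, c("chrom", "pos", "a1", "a2")]
  rownames(nonsyn) <- NULL

  fx <- list(spec = spec, layout = layout, panels = panels,
             sumstats = sumstats, genes = layout$genes,
             features = features, nonsyn = nonsyn,
             truth = layout$truth)
  if (!is.null(dir)) writeFixture(fx, dir)
  fx
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' @param fx a [makeFixture()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in names(fx$sumstats))
    writeSumstats(fx$sumstats[[a]],
                  file.path(dir, sprintf("sumstats_%s.tsv", a)))
  for (a in names(fx$panels))
    writeDosageTSV(fx$panels[[a]],
                   file.path(dir, sprintf("panel_%s.tsv", a)))
  writeGeneModels(fx$genes, file.path(dir, "genes.tsv"))
  writeFeatureMatrix(fx$features, file.path(dir, "features.tsv"))
  data.table::fwrite(
    data.frame(CHR = fx$nonsyn$chrom, BP = fx$nonsyn$pos,
               A1 = fx$nonsyn$a1, A2 = fx$nonsyn$a2),
    file.path(dir, "nonsyn.tsv"), sep = "\t")
  data.table::fwrite(fx$truth, file.path(dir, "truth_table.tsv"),
                     sep = "\t")
  manifest <- fx$spec
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "fixture_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
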