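#' Read gene models from a BED-like TSV
#'
#' Columns GENE_ID, CHR, START, END, STRAND; coordinates 1-based
#' inclusive transcription spans. Only autosomal genes are kept.
#'
#' @param path path to the TSV.
#' @return GRanges with mcols gene_id and strand set.
#' @export
readGeneModels <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  need <- c("GENE_ID", "CHR", "START", "END", "STRAND")
  if (!all(need %in% names(d)))
    stop("gene TSV needs columns: ", paste(need, collapse = ", "))
  makeGeneModels(data.frame(gene_id = d$GENE_ID, chrom = d$CHR,
                            start = d$START, end = d$END,
                            strand = d$STRAND))
}

#' Construct gene models from a data.frame
#'
#' @param d data.frame with gene_id, chrom, start, end, strand.
#' @return GRanges, autosomes only, sorted by (chrom, start).
#' @export
makeGeneModels <- function(d) {
  d <- as.data.frame(d)
  d$chrom <- suppressWarnings(as.integer(d$chrom))
  d <- d[!is.na(d$chrom) & d$chrom %in% .AUTOSOMES, , drop = FALSE]
  if (any(d$start > d$end)) stop("gene start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(d$chrom),
    ranges = IRanges::IRanges(start = d$start, end = d$end),
    strand = ifelse(d$strand %in% c("+", "-"), d$strand, "*"))
  S4Vectors::mcols(gr)$gene_id <- as.character(d$gene_id)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write gene models to the BED-like TSV dialect
#'
#' @param genes GRanges from [makeGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  out <- data.frame(
    GENE_ID = S4Vectors::mcols(genes)$gene_id,
    CHR = as.integer(as.character(GenomicRanges::seqnames(genes))),
    START = GenomicRanges::start(genes),
    END = GenomicRanges::end(genes),
    STRAND = as.character(GenomicRanges::strand(genes)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Import gene models from GFF3 gene lines
#'
#' Thin wrapper over rtracklayer's GFF import keeping `type == "gene"`
#' records on autosomes.
#'
#' @param path path to a GFF3 file.
#' @param idAttribute mcols attribute holding the gene identifier.
#' @return GRanges in the [makeGeneModels()] layout.
#' @export
importGenesFromGFF <- function(path, idAttribute = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for GFF import")
  gr <- rtracklayer::import(path)
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  makeGeneModels(data.frame(
    gene_id = S4Vectors::mcols(gr)[[idAttribute]],
    chrom = sub("^chr", "", as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))))
}

#' Map variants to gene bodies
#'
#' Assigns each variant to every gene whose transcription span (no
#' flanking window) contains its position; genes with fewer than
#' `minVariants` mapped variants are dropped and counted.
#'
#' @param x MAF-filtered [SumStats-class].
#' @param genes GRanges gene models.
#' @param minVariants minimum variants per retained gene.
#' @return list(assignments = data.frame(gene_id, row) with `row` indexing
#'   into the sumstats records; dropped = number of genes removed for
#'   having too few variants).
#' @export
mapVariantsToGenes <- function(x, genes, minVariants = 3L) {
  d <- sumstatsData(x)
  vgr <- GenomicRanges::GRanges(
    seqnames = as.character(d$chrom),
    ranges = IRanges::IRanges(start = d$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(vgr, genes, ignore.strand = TRUE)
  asg <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id[S4Vectors::subjectHits(ov)],
    row = S4Vectors::queryHits(ov))
  counts <- table(asg$gene_id)
  keep <- names(counts)[counts >= minVariants]
  dropped <- sum(counts < minVariants)
  asg <- asg[asg$gene_id %in% keep, , drop = FALSE]
  asg <- asg[order(asg$gene_id, asg$row), ]
  rownames(asg) <- NULL
  list(assignments = asg, dropped = dropped)
}

#' SNP-wise mean gene statistic
#'
#' @param zs z-statistics of a gene's mapped variants.
#' @return mean of squared z (scalar).
#' @export
snpwiseMeanStat <- function(zs) {
  if (length(zs) == 0L) stop("no variants supplied")
  mean(zs^2)
}

#' Tail probability of a weighted sum of chi-squares
#'
#' Survival function of Q = sum(lambda_i * chisq_1) at `q`, the null of
#' the SNP-wise mean statistic when the gene's variants are correlated
#' (lambdas are the eigenvalues of their LD matrix). Methods:
#' "satterthwaite" (default) moment-matches a scaled chi-square (mean
#' sum(lambda), variance 2 sum(lambda^2)); "imhof" inverts the
#' characteristic function by numerical integration; "montecarlo" uses
#' empirical draws. Results are clipped to [1e-300, 1].
#'
#' @param q observed value (K * T for a gene with K variants; >= 0).
#' @param lambdas non-negative eigenvalues (tiny negative values from
#'   finite-precision eigendecompositions are clamped to 0).
#' @param method approximation method.
#' @param nDraws Monte-Carlo draw count (method = "montecarlo").
#' @return upper-tail probability.
#' @export
weightedChisqSF <- function(q, lambdas,
                            method = c("satterthwaite", "imhof",
                                       "montecarlo"),
                            nDraws = 1e6) {
  method <- match.arg(method)
  if (any(lambdas < -1e-8)) stop("negative eigenvalues supplied")
  lambdas <- pmax(lambdas, 0)
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) stop("degenerate gene: all eigenvalues zero")
  if (q < 0) stop("q must be >= 0")
  if (diff(range(lambdas)) < 1e-12 * max(lambdas)) {
    # equal eigenvalues: exactly a scaled chi-square, no approximation
    return(min(max(pchisq(q / lambdas[1], df = length(lambdas),
                          lower.tail = FALSE), 1e-300), 1))
  }
  p <- switch(method,
    satterthwaite = {
      s1 <- sum(lambdas); s2 <- sum(lambdas^2)
      a <- s2 / s1; df <- s1^2 / s2
      pchisq(q / a, df = df, lower.tail = FALSE)
    },
    imhof = .imhofSF(q, lambdas),
    montecarlo = {
      draws <- colSums(lambdas *
        matrix(rchisq(nDraws * length(lambdas), df = 1),
               nrow = length(lambdas)))
      mean(draws > q)
    })
  min(max(p, 1e-300), 1)
}

# Imhof (1961) inversion: P(Q > q) = 1/2 + (1/pi) Int_0^inf
# sin(theta(u)) / (u rho(u)) du with theta(u) = sum(atan(lambda u))/2 -
# q u / 2 and rho(u) = prod(1 + lambda^2 u^2)^(1/4).
.imhofSF <- function(q, lambdas) {
  integrand <- function(u) {
    vapply(u, function(ui) {
      if (ui == 0) return(sum(lambdas) / 2 - q / 2)
      theta <- sum(atan(lambdas * ui)) / 2 - q * ui / 2
      lrho <- sum(log1p(lambdas^2 * ui^2)) / 4
      sin(theta) / (ui * exp(lrho))
    }, numeric(1))
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
              subdivisions = 5000L, stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (is.na(val)) {         # fall back to the moment-matched form
    s1 <- sum(lambdas); s2 <- sum(lambdas^2)
    return(pchisq(q * s1 / s2, df = s1^2 / s2, lower.tail = FALSE))
  }
  0.5 + val / pi
}

#' Probit z-score from a gene p-value
#'
#' One-sided (enrichment-direction) probit transform z = qnorm(1 - p),
#' with p clipped below at 1e-300 so z stays finite.
#'
#' @param p gene p-value(s) in (0, 1].
#' @return z-score(s).
#' @export
geneZ <- function(p) {
  p <- pmin(pmax(p, 1e-300), 1)
  qnorm(p, lower.tail = FALSE)
}

#' Gene-level association scores for one ancestry
#'
#' Maps MAF-filtered variants to gene bodies, computes the SNP-wise mean
#' statistic per gene, evaluates its LD-aware weighted-chi-square null
#' (eigenvalues from the ancestry-matched panel restricted to the gene's
#' variants, PSD-stabilized), and converts p-values to probit z-scores.
#'
#' @param x [SumStats-class] for one ancestry (MAF-filtered and
#'   harmonized to `panel`).
#' @param panel ancestry-matched [GenotypePanel-class].
#' @param genes GRanges gene models.
#' @param minVariants minimum mapped variants per gene.
#' @param method null-approximation method, see [weightedChisqSF()].
#' @return data.frame(gene_id, chrom, n_variants, stat, p, z).
#' @export
geneAssociation <- function(x, panel, genes, minVariants = 3L,
                            method = "satterthwaite") {
  d <- sumstatsData(x)
  mp <- mapVariantsToGenes(x, genes, minVariants)
  asg <- mp$assignments
  if (nrow(asg) == 0L)
    return(data.frame(gene_id = character(0), chrom = integer(0),
                      n_variants = integer(0), stat = numeric(0),
                      p = numeric(0), z = numeric(0)))
  rows_by_gene <- split(asg$row, asg$gene_id)
  res <- lapply(names(rows_by_gene), function(g) {
    rows <- rows_by_gene[[g]]
    zs <- d$z[rows]
    Tstat <- snpwiseMeanStat(zs)
    R <- ldCorrelation(panel, d[rows, c("chrom", "pos", "a1", "a2")])
    lam <- eigen(ldr(R), symmetric = TRUE, only.values = TRUE)$values
    p <- weightedChisqSF(length(zs) * Tstat, lam, method = method)
    data.frame(gene_id = g, chrom = d$chrom[rows[1]],
               n_variants = length(zs), stat = Tstat, p = p,
               z = geneZ(p))
  })
  out <- do.call(rbind, res)
  out[order(out$chrom, out$gene_id), , drop = FALSE]
}

#' Meta-analyze per-ancestry gene z-scores
#'
#' sqrt(N)-weighted Stouffer combination of gene z-scores across
#' ancestries (see [sqrtNZMeta()]); the total study effective sample size
#' per ancestry supplies the weights. Genes present in a subset of
#' ancestries are combined over that subset.
#'
#' @param scoreList named list of [geneAssociation()] outputs, one per
#'   ancestry.
#' @param ns named numeric vector of per-ancestry effective sample sizes.
#' @return data.frame(gene_id, chrom, z_<ancestry>..., z_meta).
#' @export
metaGeneZ <- function(scoreList, ns) {
  anc <- names(scoreList)
  stopifnot(!is.null(anc), all(anc %in% names(ns)))
  ids <- unique(unlist(lapply(scoreList, function(s) s$gene_id)))
  Z <- sapply(scoreList, function(s) s$z[match(ids, s$gene_id)])
  Z <- matrix(Z, ncol = length(anc),
              dimnames = list(NULL, paste0("z_", anc)))
  chrom <- rep(NA_integer_, length(ids))
  for (s in scoreList) {
    hit <- match(s$gene_id, ids)
    chrom[hit] <- s$chrom
  }
  W <- matrix(rep(sqrt(ns[anc]), each = length(ids)), ncol = length(anc))
  pres <- !is.na(Z)
  z_meta <- rowSums(ifelse(pres, W * Z, 0)) /
    sqrt(rowSums(ifelse(pres, W^2, 0)))
  data.frame(gene_id = ids, chrom = chrom, Z, z_meta = z_meta,
             row.names = NULL)
}
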