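#' Construct a genotype reference panel
#'
#' @param dosages samples x variants matrix with entries in 0/1/2.
#' @param variants data.frame with chrom, pos, a1, a2 in column order.
#' @param sampleAncestry per-sample ancestry labels.
#' @param sampleIds sample identifiers (defaults to S1..Sn).
#' @return a [GenotypePanel-class]. Monomorphic columns are allowed at
#'   construction but flagged via `monomorphicVariants()`.
#' @export
makeGenotypePanel <- function(dosages, variants, sampleAncestry,
                              sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%d", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants)
  variants$chrom <- as.integer(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  colnames(dosages) <- variantId(variants)
  rownames(dosages) <- sampleIds
  new("GenotypePanel", dosages = dosages, variants = variants,
      sampleAncestry = as.character(sampleAncestry),
      sampleIds = as.character(sampleIds))
}

#' Indices of monomorphic variant columns in a panel
#'
#' @param panel a [GenotypePanel-class].
#' @return integer indices of columns with zero dosage variance.
#' @export
monomorphicVariants <- function(panel) {
  d <- dosages(panel)
  which(apply(d, 2, function(col) max(col) == min(col)))
}

#' Panel effect-allele (a1) frequencies
#'
#' @param panel a [GenotypePanel-class].
#' @return named numeric vector of a1 dosage frequencies, names
#'   "chrom:pos:a1:a2".
#' @export
panelAlleleFreq <- function(panel) {
  f <- colMeans(dosages(panel)) / 2
  names(f) <- variantId(variantKeys(panel))
  f
}

#' Build an ancestry-mixed reference panel matching target proportions
#'
#' Includes the limiting ancestry (the one whose full sample implies the
#' smallest total panel) in full and subsamples the others uniformly
#' without replacement so realized shares match the targets to the nearest
#' whole sample.
#'
#' @param panels named list of [GenotypePanel-class], one per ancestry; all
#'   must hold the same variants in the same order.
#' @param targetShare named numeric vector of target proportions (sums
#'   to 1), names matching `panels`.
#' @param seed integer seed for the subsampling.
#' @param includeAll optional ancestry name forced to be included in full
#'   (overrides the automatic limiting-ancestry choice).
#' @return list(panel = mixed [GenotypePanel-class], counts = realized
#'   per-ancestry sample counts, total = total samples).
#' @export
buildMixedPanel <- function(panels, targetShare, seed = 1L,
                            includeAll = NULL) {
  stopifnot(is.list(panels), length(panels) >= 1L)
  anc <- names(panels)
  if (is.null(anc) || !all(anc %in% names(targetShare)))
    stop("panels and targetShare must share ancestry names")
  s <- targetShare[anc]
  if (abs(sum(s) - 1) > 1e-8) stop("target shares must sum to 1")
  navail <- vapply(panels, function(p) nrow(dosages(p)), integer(1))

  if (is.null(includeAll)) {
    includeAll <- anc[which.min(navail / s)]
  } else if (!includeAll %in% anc) {
    stop("includeAll ancestry not among panels: ", includeAll)
  }
  total <- navail[includeAll] / s[includeAll]
  need <- round(total * s)
  need[includeAll] <- navail[includeAll]
  over <- need > navail
  if (any(over)) {
    a <- anc[over][1]
    max_share <- navail[a] / (navail[a] + navail[includeAll])
    stop(sprintf(
      "target share %.4f for ancestry %s unattainable (%d available; maximum attainable share with %s in full is about %.4f)",
      s[a], a, navail[a], includeAll, max_share))
  }

  set.seed(.deriveSeed(seed, 17L))
  picked <- lapply(anc, function(a) {
    n <- navail[a]
    if (need[a] == n) seq_len(n) else sort(sample.int(n, need[a]))
  })
  names(picked) <- anc

  ref_var <- variantKeys(panels[[1]])
  dmat <- do.call(rbind, lapply(anc, function(a) {
    pv <- variantKeys(panels[[a]])
    if (!identical(variantId(pv), variantId(ref_var)))
      stop("panels hold different variants")
    dosages(panels[[a]])[picked[[a]], , drop = FALSE]
  }))
  labels <- rep(anc, times = vapply(picked, length, integer(1)))
  ids <- unlist(lapply(anc, function(a)
    paste0(a, "_", rownames(dosages(panels[[a]]))[picked[[a]]])),
    use.names = FALSE)
  list(panel = makeGenotypePanel(dmat, ref_var, labels, ids),
       counts = vapply(picked, length, integer(1)),
       total = sum(vapply(picked, length, integer(1))))
}

#' Signed LD correlation between panel variants
#'
#' Pearson correlation of unphased dosage columns, symmetrized and (by
#' default) shifted to positive semi-definiteness so downstream Cholesky
#' factorizations cannot fail.
#'
#' @param panel a [GenotypePanel-class].
#' @param keys optional data.frame of variant keys (chrom,pos,a1,a2) or
#'   character vector of variant ids selecting an ordered subset; default
#'   all panel variants.
#' @param stabilize logical; apply the PSD shift.
#' @return an [LDMatrix-class].
#' @export
ldCorrelation <- function(panel, keys = NULL, stabilize = TRUE) {
  pv <- variantKeys(panel)
  ids <- variantId(pv)
  if (is.null(keys)) {
    sel <- seq_len(nrow(pv))
  } else {
    want <- if (is.character(keys)) keys else variantId(keys)
    sel <- match(want, ids)
    if (anyNA(sel))
      stop("variants absent from panel: ",
           paste(head(want[is.na(sel)], 5L), collapse = ", "))
  }
  d <- dosages(panel)[, sel, drop = FALSE]
  if (nrow(d) < 2L) stop("need >= 2 samples for LD")
  mono <- which(apply(d, 2, function(col) max(col) == min(col)))
  if (length(mono) > 0L)
    stop("monomorphic variant(s) among keys: ",
         paste(head(colnames(d)[mono], 10L), collapse = ", "))
  r <- cor(d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (stabilize) r <- .psdStabilize(r)$r
  new("LDMatrix", r = r, variants = pv[sel, , drop = FALSE])
}

# ---- PLINK-1 binary trio ----------------------------------------------

#' Write a panel as a PLINK-1 binary trio (.bed/.bim/.fam)
#'
#' SNP-major .bed (magic 0x6c 0x1b 0x01). Dosages count the .bim allele-1
#' (our a1). Ancestry labels are stored in the .fam family-id column.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix path prefix (files prefix.bed/.bim/.fam are written).
#' @return `prefix`, invisibly.
#' @export
writePlinkPanel <- function(panel, prefix) {
  v <- variantKeys(panel)
  d <- dosages(panel)
  n <- nrow(d)
  bim <- data.frame(v$chrom, variantId(v), 0L, v$pos, v$a1, v$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  fam <- data.frame(sampleAncestry(panel), panel@sampleIds, 0L, 0L, 0L,
                    -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  # 2-bit codes per sample: a1-dosage 2 -> 00, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = ncol(d))
  code[d == 2] <- 0L
  code[d == 1] <- 2L
  npad <- 4L * ceiling(n / 4L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(ncol(d))) {
    cj <- c(code[, j], rep(0L, npad - n))
    bytes <- cj[seq(1, npad, by = 4)] +
      cj[seq(2, npad, by = 4)] * 4L +
      cj[seq(3, npad, by = 4)] * 16L +
      cj[seq(4, npad, by = 4)] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK-1 binary trio into a genotype panel
#'
#' Supports SNP-major .bed files with no missing genotypes; the .fam
#' family-id column is taken as the ancestry label.
#'
#' @param prefix path prefix of the .bed/.bim/.fam trio.
#' @return a [GenotypePanel-class] with dosages counting the .bim allele 1.
#' @export
readPlinkPanel <- function(prefix) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           data.table = FALSE)
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE,
                           data.table = FALSE)
  variants <- data.frame(chrom = as.integer(bim[[1]]),
                         pos = as.integer(bim[[4]]),
                         a1 = as.character(bim[[5]]),
                         a2 = as.character(bim[[6]]))
  n <- nrow(fam); m <- nrow(bim)
  bpv <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bpv * m)
  if (length(raw) < 3 + bpv * m) stop("truncated .bed file")
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK-1 .bed file")
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, little-endian within each byte: rows of `per_byte`
  # are the four samples packed into one byte, columns are bytes
  per_byte <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                    (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  codes <- matrix(as.vector(per_byte), nrow = bpv * 4L)[seq_len(n), ,
                                                        drop = FALSE]
  if (any(codes == 1L)) stop("missing genotypes are not supported")
  dos <- matrix(0, nrow = n, ncol = m)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  makeGenotypePanel(dos, variants, as.character(fam[[1]]),
                    as.character(fam[[2]]))
}

# ---- plain dosage TSV -------------------------------------------------

#' Write a panel as a plain dosage TSV
#'
#' Rows are samples; the first two columns are SAMPLE_ID and ANCESTRY, the
#' remaining columns are variant ids "chrom:pos:a1:a2" holding a1-dosages.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDosageTSV <- function(panel, path) {
  d <- as.data.frame(dosages(panel))
  out <- cbind(data.frame(SAMPLE_ID = panel@sampleIds,
                          ANCESTRY = sampleAncestry(panel)), d)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a plain dosage TSV into a genotype panel
#'
#' @param path path to a TSV written by [writeDosageTSV()].
#' @return a [GenotypePanel-class].
#' @export
readDosageTSV <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  vcols <- setdiff(names(raw), c("SAMPLE_ID", "ANCESTRY"))
  parts <- strsplit(vcols, ":", fixed = TRUE)
  variants <- data.frame(
    chrom = as.integer(vapply(parts, `[`, "", 1L)),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    a1 = vapply(parts, `[`, "", 3L),
    a2 = vapply(parts, `[`, "", 4L))
  makeGenotypePanel(as.matrix(raw[, vcols, drop = FALSE]), variants,
                    raw$ANCESTRY, raw$SAMPLE_ID)
}
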