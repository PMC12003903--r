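#' Read GWAS summary statistics from a TSV file
#'
#' Reads the tab-separated summary-statistics dialect (header row, columns
#' CHR, BP, A1, A2, FREQ, BETA, SE, P, N_EFF; gzip transparent), sorts by
#' (chromosome, position, alleles), and deduplicates variant keys keeping
#' the record with the smallest p-value.
#'
#' @param path path to the TSV (optionally gzipped).
#' @param ancestry ancestry label stored on the table.
#' @param columnMap named character vector mapping the canonical names
#'   (CHR, BP, A1, A2, FREQ, BETA, SE, P, N_EFF, optionally Z) to the file's
#'   column names. Defaults to the identity mapping.
#' @return a [SumStats-class] object; z is recomputed as beta/se.
#' @export
readSumstats <- function(path, ancestry = NA_character_, columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dflt <- c(CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2", FREQ = "FREQ",
            BETA = "BETA", SE = "SE", P = "P", N_EFF = "N_EFF")
  map <- dflt
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  missing <- map[!(map %in% names(raw))]
  if (length(missing) > 0L)
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (mapped from %s)", missing, names(missing)),
               collapse = ", "))
  d <- data.frame(
    chrom = suppressWarnings(as.integer(raw[[map["CHR"]]])),
    pos   = suppressWarnings(as.integer(raw[[map["BP"]]])),
    a1    = toupper(as.character(raw[[map["A1"]]])),
    a2    = toupper(as.character(raw[[map["A2"]]])),
    af    = as.numeric(raw[[map["FREQ"]]]),
    beta  = as.numeric(raw[[map["BETA"]]]),
    se    = as.numeric(raw[[map["SE"]]]),
    p     = as.numeric(raw[[map["P"]]]),
    n_eff = as.numeric(raw[[map["N_EFF"]]]),
    stringsAsFactors = FALSE)
  bad <- which(is.na(d$chrom) | is.na(d$pos) | is.na(d$af) | is.na(d$beta) |
                 is.na(d$se) | is.na(d$p))
  if (length(bad) > 0L)
    stop("unparseable row(s) at line(s): ",
         paste(head(bad + 1L, 10L), collapse = ", "))
  makeSumStats(d, ancestry = ancestry, provenance = path)
}

#' Construct a SumStats object from a data.frame
#'
#' Sorts, deduplicates (keeping the smallest p per variant key, with a
#' message for every drop), and caches z = beta/se.
#'
#' @param d data.frame with chrom, pos, a1, a2, af, beta, se, p, n_eff.
#' @param ancestry ancestry label.
#' @param provenance free text recorded on the object.
#' @return a [SumStats-class] object.
#' @export
makeSumStats <- function(d, ancestry = NA_character_, provenance = "") {
  d <- as.data.frame(d)
  d$chrom <- as.integer(d$chrom)
  d$pos <- as.integer(d$pos)
  d$z <- d$beta / d$se
  key <- variantId(d)
  if (anyDuplicated(key)) {
    o <- order(d$p)
    dup <- duplicated(key[o])
    dropped <- sum(dup)
    d <- d[o, ][!dup, ]
    message(dropped, " duplicate variant record(s) dropped (kept smallest p)")
  }
  d <- d[order(d$chrom, d$pos, d$a1, d$a2), .SUMSTATS_COLS]
  rownames(d) <- NULL
  new("SumStats", data = d, ancestry = ancestry, provenance = provenance)
}

#' Write summary statistics in the TSV dialect
#'
#' @param x a [SumStats-class] object.
#' @param path output path; ".gz" suffix compresses.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  d <- sumstatsData(x)
  out <- data.frame(CHR = d$chrom, BP = d$pos, A1 = d$a1, A2 = d$a2,
                    FREQ = d$af, BETA = d$beta, SE = d$se, P = d$p,
                    N_EFF = d$n_eff)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Harmonize summary statistics to a reference panel's allele orientation
#'
#' Matches records to panel variants by position. Records whose allele pair
#' equals the panel's in swapped order have beta negated and af replaced by
#' 1 - af; records absent from the panel, records whose allele pair is
#' incompatible with the panel's, and strand-ambiguous records (A/T or C/G)
#' with af inside the ambiguity window are dropped and counted.
#'
#' @param x a [SumStats-class] object.
#' @param panel a [GenotypePanel-class] (or anything with `variantKeys()`).
#' @param ambiguityWindow open frequency interval inside which
#'   strand-ambiguous records are dropped.
#' @return list(sumstats = harmonized [SumStats-class], counts = named
#'   integer vector with kept / flipped / absent / mismatch / ambiguous).
#' @export
harmonizeToPanel <- function(x, panel, ambiguityWindow = c(0.4, 0.6)) {
  d <- sumstatsData(x)
  pv <- variantKeys(panel)
  counts <- c(kept = 0L, flipped = 0L, absent = 0L, mismatch = 0L,
              ambiguous = 0L)

  amb <- .isStrandAmbiguous(d$a1, d$a2) &
    d$af > ambiguityWindow[1] & d$af < ambiguityWindow[2]
  counts["ambiguous"] <- sum(amb)
  d <- d[!amb, , drop = FALSE]

  idx <- match(.posId(d), .posId(pv))
  absent <- is.na(idx)
  counts["absent"] <- sum(absent)
  d <- d[!absent, , drop = FALSE]
  idx <- idx[!absent]

  same <- d$a1 == pv$a1[idx] & d$a2 == pv$a2[idx]
  swapped <- d$a1 == pv$a2[idx] & d$a2 == pv$a1[idx]
  counts["mismatch"] <- sum(!same & !swapped)
  counts["kept"] <- sum(same)
  counts["flipped"] <- sum(swapped)

  if (any(swapped)) {
    d$beta[swapped] <- -d$beta[swapped]
    d$z[swapped] <- -d$z[swapped]
    d$af[swapped] <- 1 - d$af[swapped]
    tmp <- d$a1[swapped]
    d$a1[swapped] <- d$a2[swapped]
    d$a2[swapped] <- tmp
  }
  d <- d[same | swapped, , drop = FALSE]
  d <- d[order(d$chrom, d$pos, d$a1, d$a2), , drop = FALSE]
  rownames(d) <- NULL
  list(sumstats = new("SumStats", data = d, ancestry = ancestry(x),
                      provenance = x@provenance),
       counts = counts)
}

#' Allele-frequency quality control against panel frequencies
#'
#' Two sequential filters on records harmonized to the panel orientation:
#' first remove records whose effect-allele frequency differs from the
#' panel frequency by more than `diffThresh` (absolute), then remove
#' records whose frequency ratio (symmetric, max of the two directions)
#' exceeds `foldThresh`. Panel frequencies of exactly 0 or 1 are counted
#' separately as monomorphic and removed under the fold rule.
#'
#' @param x harmonized [SumStats-class].
#' @param panelAF named numeric vector of panel effect-allele frequencies,
#'   names being variant ids "chrom:pos:a1:a2" (see [panelAlleleFreq()]).
#' @param diffThresh absolute-difference threshold (strict >).
#' @param foldThresh fold-change threshold (strict >).
#' @return list(sumstats = filtered table, counts = named integer vector
#'   with diff / fold / monomorphic removals).
#' @export
qcAlleleFrequency <- function(x, panelAF, diffThresh = 0.1,
                              foldThresh = 12) {
  d <- sumstatsData(x)
  paf <- panelAF[variantId(d)]
  if (anyNA(paf))
    stop("panelAF missing for ", sum(is.na(paf)), " variant(s)")
  counts <- c(diff = 0L, fold = 0L, monomorphic = 0L)

  rm_diff <- abs(d$af - paf) > diffThresh
  counts["diff"] <- sum(rm_diff)
  d <- d[!rm_diff, , drop = FALSE]
  paf <- paf[!rm_diff]

  mono <- paf <= 0 | paf >= 1
  fold <- rep(FALSE, nrow(d))
  ok <- !mono
  fold[ok] <- pmax(d$af[ok] / paf[ok], paf[ok] / d$af[ok]) > foldThresh
  counts["monomorphic"] <- sum(mono)
  counts["fold"] <- sum(fold)
  d <- d[!(mono | fold), , drop = FALSE]
  rownames(d) <- NULL
  list(sumstats = new("SumStats", data = d, ancestry = ancestry(x),
                      provenance = x@provenance),
       counts = counts)
}

#' Minor-allele-frequency filter
#'
#' Keeps records with min(af, 1 - af) strictly greater than `mafMin`
#' (the ">1 percent" rule read literally: MAF exactly at the threshold is
#' removed).
#'
#' @param x a [SumStats-class].
#' @param mafMin minimum minor-allele frequency (strict >).
#' @return filtered [SumStats-class].
#' @export
mafFilter <- function(x, mafMin = 0.01) {
  d <- sumstatsData(x)
  keep <- pmin(d$af, 1 - d$af) > mafMin
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  new("SumStats", data = d, ancestry = ancestry(x),
      provenance = x@provenance)
}
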