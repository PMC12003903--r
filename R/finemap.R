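#' Wakefield log approximate Bayes factor
#'
#' For a variant with z-statistic z and standard error se, and a normal
#' effect-size prior with standard deviation `priorSd` (W = priorSd^2):
#' labf = 0.5 log(1 - r) + 0.5 z^2 r with r = W / (W + se^2). A prior sd
#' of 0 gives labf = 0 (Bayes factor 1) for any z.
#'
#' @param z z-statistic(s).
#' @param se standard error(s) of beta (> 0).
#' @param priorSd prior standard deviation on the effect size (log-odds
#'   scale for case-control traits; the conventional default is 0.2).
#' @return natural-log approximate Bayes factor(s), vectorized.
#' @export
wakefieldLogABF <- function(z, se, priorSd = 0.2) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(priorSd < 0)) stop("priorSd must be >= 0")
  W <- priorSd^2
  r <- W / (W + se^2)
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

#' Posterior inclusion probabilities from log Bayes factors
#'
#' Normalizes exp(labf) over variants under the exactly-one-causal-variant
#' assumption, using a log-sum-exp shift so the computation is stable for
#' labf values up to and beyond 700.
#'
#' @param labfs numeric vector of log approximate Bayes factors.
#' @return PIP vector summing to 1.
#' @export
pipsFromLabf <- function(labfs) {
  if (length(labfs) == 0L) stop("no variants supplied")
  exp(labfs - .logsumexp(labfs))
}

#' Fine-map one isolated signal
#'
#' Computes Wakefield log-ABFs and PIPs for every variant of an isolated
#' signal, forms the minimal descending-PIP credible set with cumulative
#' mass at least `mass` (ties in PIP broken by ascending position), the
#' PIP-weighted center of the set, and the locus interval (credible-set
#' span padded by `padBp` on each side, clamped at position 1).
#'
#' @param tab data.frame in the sumstats layout (chrom, pos, a1, a2, z,
#'   se, ...), typically one element of [isolateSignals()] output; an
#'   optional `signal_id` column names the signal.
#' @param priorSd prior effect-size standard deviation.
#' @param mass credible-set target mass.
#' @param padBp locus padding in bp.
#' @return a [CredibleSet-class].
#' @export
fineMapSignal <- function(tab, priorSd = 0.2, mass = 0.95, padBp = 3e5) {
  if (nrow(tab) == 0L) stop("empty signal table")
  sid <- if ("signal_id" %in% names(tab)) tab$signal_id[1] else
    sprintf("%d:%d", tab$chrom[which.max(abs(tab$z))],
            tab$pos[which.max(abs(tab$z))])
  labf <- wakefieldLogABF(tab$z, tab$se, priorSd)
  pip <- pipsFromLabf(labf)
  abf <- data.frame(tab[, c("chrom", "pos", "a1", "a2", "z")],
                    labf = labf, pip = pip)
  cs_idx <- credibleSetIndices(pip, tab$pos, mass)
  abf$inCS <- seq_len(nrow(abf)) %in% cs_idx
  members <- abf[cs_idx, , drop = FALSE]
  rownames(members) <- NULL
  center <- pipWeightedCenter(members$pos, members$pip)
  span <- range(members$pos)
  locus <- GenomicRanges::GRanges(
    seqnames = as.character(members$chrom[1]),
    ranges = IRanges::IRanges(start = max(1, span[1] - padBp),
                              end = span[2] + padBp))
  S4Vectors::mcols(locus)$signal_id <- sid
  new("CredibleSet", signalId = sid, abf = abf, members = members,
      mass = sum(members$pip), center = center, locus = locus)
}

#' Minimal descending-PIP credible-set membership
#'
#' @param pips normalized PIP vector.
#' @param pos positions used for tie-breaking (ascending).
#' @param mass target cumulative mass.
#' @return integer indices of the members, ordered by descending PIP.
#' @export
credibleSetIndices <- function(pips, pos, mass = 0.95) {
  o <- order(-pips, pos)
  k <- which(cumsum(pips[o]) >= mass - 1e-12)[1]
  if (is.na(k)) k <- length(o)
  o[seq_len(k)]
}

#' PIP-weighted average position of credible-set members
#'
#' Member PIPs are renormalized to sum to 1 within the set; the weighted
#' mean position is rounded to the nearest base pair.
#'
#' @param pos member positions.
#' @param pips member PIPs (any positive scale).
#' @return integer-valued center position.
#' @export
pipWeightedCenter <- function(pos, pips) {
  round(sum(pos * pips / sum(pips)))
}

#' Locus interval around a credible set
#'
#' @param cs a [CredibleSet-class].
#' @param padBp padding on each side of the credible-set span.
#' @return GRanges of length 1 (start clamped at 1).
#' @export
defineLocus <- function(cs, padBp = 3e5) {
  span <- range(credibleMembers(cs)$pos)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(credibleMembers(cs)$chrom[1]),
    ranges = IRanges::IRanges(start = max(1, span[1] - padBp),
                              end = span[2] + padBp))
  S4Vectors::mcols(gr)$signal_id <- cs@signalId
  gr
}

#' Export a fine-mapped signal for regional plotting
#'
#' Emits a LocusZoom-style table: every variant's p-value plus its r^2 to
#' the credible set's top-PIP variant.
#'
#' @param cs a [CredibleSet-class].
#' @param tab the signal's sumstats data.frame (as passed to
#'   [fineMapSignal()]).
#' @param panel a [GenotypePanel-class] for r^2 to the lead.
#' @return data.frame with CHR, BP, A1, A2, P, R2_LEAD, IN_CS.
#' @export
locusZoomExport <- function(cs, tab, panel) {
  abf <- abfTable(cs)
  lead <- credibleMembers(cs)[1, ]
  ids <- variantId(variantKeys(panel))
  lead_col <- match(variantId(lead), ids)
  var_col <- match(variantId(tab), ids)
  if (is.na(lead_col) || anyNA(var_col))
    stop("variants absent from the panel")
  dos <- dosages(panel)
  r <- suppressWarnings(
    as.vector(cor(dos[, lead_col], dos[, var_col, drop = FALSE])))
  r[is.na(r)] <- 0
  data.frame(CHR = tab$chrom, BP = tab$pos, A1 = tab$a1, A2 = tab$a2,
             P = tab$p, R2_LEAD = r^2,
             IN_CS = abf$inCS[match(variantId(tab), variantId(abf))])
}
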