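#' Greedy LD clumping of significant variants
#'
#' Iteratively takes the unassigned genome-wide-significant variant with
#' the smallest p-value as a lead (ties broken by smaller chromosome then
#' position) and assigns to it every unassigned variant on the same
#' chromosome within the window whose squared correlation with the lead
#' is at least `r2Thresh`. Members are not p-filtered.
#'
#' @param x a [SumStats-class] harmonized to `panel`.
#' @param panel a [GenotypePanel-class] providing LD.
#' @param pThresh significance threshold for leads.
#' @param r2Thresh minimum r^2 to the lead for membership.
#' @param windowBp total window size in bp; membership requires
#'   |pos_member - pos_lead| <= windowBp/2 when `windowMode = "total"`
#'   (the named tool's kb semantics), or <= windowBp when "flank".
#' @param windowMode "total" or "flank"; see `windowBp`.
#' @return list of clumps, each a list with `lead` (1-row key data.frame),
#'   `members` (data.frame of keys with p and r2 to lead), `chrom`, and
#'   `span` (min/max member position).
#' @export
greedyClump <- function(x, panel, pThresh = 5e-8, r2Thresh = 0.1,
                        windowBp = 3e6, windowMode = c("total", "flank")) {
  windowMode <- match.arg(windowMode)
  flank <- if (windowMode == "total") windowBp / 2 else windowBp
  d <- sumstatsData(x)
  if (nrow(d) == 0L) return(list())
  pv <- variantKeys(panel)
  col <- match(variantId(d), variantId(pv))
  if (anyNA(col)) stop("table contains variants absent from the panel")
  dos <- dosages(panel)

  assigned <- rep(FALSE, nrow(d))
  clumps <- list()
  repeat {
    cand <- which(!assigned & d$p < pThresh)
    if (length(cand) == 0L) break
    lead <- cand[order(d$p[cand], d$chrom[cand], d$pos[cand])][1]
    inwin <- which(!assigned & d$chrom == d$chrom[lead] &
                     abs(d$pos - d$pos[lead]) <= flank)
    r <- suppressWarnings(
      as.vector(cor(dos[, col[lead]], dos[, col[inwin], drop = FALSE])))
    r[is.na(r)] <- 0           # monomorphic member column: no LD evidence
    take <- inwin[r^2 >= r2Thresh | inwin == lead]
    r2 <- (r^2)[match(take, inwin)]
    assigned[take] <- TRUE
    members <- data.frame(d[take, c("chrom", "pos", "a1", "a2", "p")],
                          r2 = r2, row.names = NULL)
    members <- members[order(members$pos), ]
    rownames(members) <- NULL
    clumps[[length(clumps) + 1L]] <- list(
      lead = d[lead, c("chrom", "pos", "a1", "a2", "p")],
      members = members,
      chrom = d$chrom[lead],
      span = range(members$pos))
  }
  clumps
}

#' Expand clumps into padded, merged regions
#'
#' Pads each clump span by `padBp` on either side, clamps at position 1,
#' and merges overlapping or touching padded intervals on the same
#' chromosome transitively.
#'
#' @param clumps output of [greedyClump()].
#' @param padBp padding in bp on each side.
#' @return data.frame with chrom, start, end (1-based closed) and a
#'   list-column `clumpIdx` of the source clump indices, sorted by
#'   (chrom, start).
#' @export
defineRegions <- function(clumps, padBp = 5e5) {
  if (length(clumps) == 0L)
    return(data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0)))
  spans <- data.frame(
    chrom = vapply(clumps, function(cl) cl$chrom, integer(1)),
    start = pmax(1, vapply(clumps, function(cl) cl$span[1], numeric(1)) -
                   padBp),
    end = vapply(clumps, function(cl) cl$span[2], numeric(1)) + padBp,
    idx = seq_along(clumps))
  out <- list()
  for (ch in sort(unique(spans$chrom))) {
    s <- spans[spans$chrom == ch, ]
    merged <- .mergeIntervals(s$start, s$end)
    for (i in seq_len(nrow(merged))) {
      src <- s$idx[s$start <= merged$end[i] & s$end >= merged$start[i]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = merged$start[i], end = merged$end[i],
        clumpIdx = I(list(src)))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Conditional z-statistic of a focal variant given selected hits
#'
#' Summary-statistics conditional analysis on the standardized (per-SD)
#' scale: z_cond = (z_f - R_fS R_SS^-1 z_S) / sqrt(1 - R_fS R_SS^-1 R_Sf).
#' With an empty selected set the marginal z is returned.
#'
#' @param zAll numeric z-vector for all region variants, aligned with `R`.
#' @param R [LDMatrix-class] or plain correlation matrix over the same
#'   variants.
#' @param selected integer indices of the conditioning hits.
#' @param focal integer index of the focal variant (not in `selected`).
#' @param r2Collinear collinearity cutoff: if the focal variant's variance
#'   explained by the selected set exceeds this, an error is raised.
#' @param varFloor lower floor on the conditional variance.
#' @return conditional z (scalar).
#' @export
conditionalZ <- function(zAll, R, selected, focal, r2Collinear = 0.9,
                         varFloor = 1e-6) {
  if (is(R, "LDMatrix")) R <- ldr(R)
  if (focal %in% selected) stop("focal variant is in the selected set")
  if (length(selected) == 0L) return(zAll[focal])
  Rss <- R[selected, selected, drop = FALSE]
  rfs <- R[focal, selected, drop = FALSE]
  w <- solve(Rss, t(rfs))
  expl <- as.numeric(rfs %*% w)
  den2 <- 1 - expl
  if (den2 < 1 - r2Collinear)
    stop(sprintf(
      "focal variant %d is collinear with the selected set (r2 = %.4f)",
      focal, expl))
  num <- zAll[focal] - as.numeric(zAll[selected] %*% w)
  num / sqrt(max(den2, varFloor))
}

# joint z-statistics of a selected set: b_joint = R_SS^-1 z_S on the
# per-SD scale, var(b_joint) = R_SS^-1, so z_j = b_j / sqrt((R_SS^-1)_jj)
.jointZ <- function(zS, Rss) {
  Rinv <- chol2inv(chol(Rss))
  b <- as.numeric(Rinv %*% zS)
  b / sqrt(diag(Rinv))
}

#' Stepwise selection of jointly significant independent hits
#'
#' Forward selection on summary statistics: start from the smallest-p
#' variant; repeatedly evaluate the conditional z of every candidate not
#' collinear (r^2 > `r2Collinear`) with the selected set and add the
#' candidate with the smallest conditional p if it is below `pEntry`.
#' At convergence joint statistics over the selected set are computed and
#' hits with joint p above `pEntry` are dropped (worst first, refitting
#' after each drop).
#'
#' @param x region [SumStats-class] (or its data.frame), row-aligned with
#'   `R`.
#' @param R [LDMatrix-class] or correlation matrix for the region.
#' @param pEntry entry/retention significance threshold.
#' @param r2Collinear collinearity cutoff for candidates.
#' @return data.frame of hits: chrom, pos, a1, a2, index (row in the
#'   region table), joint_z, joint_p, joint_beta, joint_se; zero rows if
#'   nothing is significant.
#' @export
stepwiseSelect <- function(x, R, pEntry = 5e-8, r2Collinear = 0.9) {
  d <- if (is(x, "SumStats")) sumstatsData(x) else as.data.frame(x)
  if (is(R, "LDMatrix")) R <- ldr(R)
  stopifnot(nrow(d) == nrow(R))
  z <- d$z
  ord <- order(d$p, d$chrom, d$pos)
  empty <- data.frame(chrom = integer(0), pos = integer(0),
                      a1 = character(0), a2 = character(0),
                      index = integer(0), joint_z = numeric(0),
                      joint_p = numeric(0), joint_beta = numeric(0),
                      joint_se = numeric(0))
  if (d$p[ord[1]] >= pEntry) return(empty)
  selected <- ord[1]

  repeat {
    cand <- setdiff(seq_len(nrow(d)), selected)
    if (length(cand) == 0L) break
    maxr2 <- apply(R[cand, selected, drop = FALSE]^2, 1, max)
    cand <- cand[maxr2 <= r2Collinear]
    if (length(cand) == 0L) break
    zc <- vapply(cand, function(j) {
      tryCatch(conditionalZ(z, R, selected, j, r2Collinear),
               error = function(e) 0)
    }, numeric(1))
    pc <- .pFromZ(zc)
    best <- order(pc, d$chrom[cand], d$pos[cand])[1]
    if (pc[best] >= pEntry) break
    selected <- c(selected, cand[best])
  }

  # backward pruning on joint statistics
  repeat {
    Rss <- R[selected, selected, drop = FALSE]
    zj <- .jointZ(z[selected], Rss)
    pj <- .pFromZ(zj)
    if (length(selected) == 1L || max(pj) <= pEntry) {
      if (max(pj) > pEntry) return(empty)   # lone hit lost significance
      break
    }
    worst <- which.max(pj)
    selected <- selected[-worst]
  }
  o <- order(d$chrom[selected], d$pos[selected])
  selected <- selected[o]
  Rss <- R[selected, selected, drop = FALSE]
  zj <- .jointZ(z[selected], Rss)
  data.frame(d[selected, c("chrom", "pos", "a1", "a2")],
             index = selected, joint_z = zj, joint_p = .pFromZ(zj),
             joint_beta = zj * d$se[selected], joint_se = d$se[selected],
             row.names = NULL)
}

#' Leave-one-hit-out conditioning to isolate each signal
#'
#' For each selected hit h the statistics of every region variant are
#' conditioned on the other selected hits, so each returned table carries
#' only h's signal. Conditional beta is reconstructed as z_cond * se with
#' se unchanged (per-SD scale). With a single hit the input table is
#' returned verbatim. Variants collinear with the conditioning set
#' (including the other hits themselves) are dropped and counted.
#'
#' @param x region [SumStats-class] (or data.frame), row-aligned with `R`.
#' @param R [LDMatrix-class] or correlation matrix.
#' @param hits data.frame from [stepwiseSelect()] (needs `index`).
#' @param r2Collinear collinearity cutoff for conditioned variants.
#' @param varFloor floor on the conditional variance.
#' @return named list (one entry per signal id "chrom:pos") of data.frames
#'   in the sumstats layout plus `signal_id`; each has an attribute
#'   `dropped` counting collinear variants removed.
#' @export
isolateSignals <- function(x, R, hits, r2Collinear = 0.9,
                           varFloor = 1e-6) {
  d <- if (is(x, "SumStats")) sumstatsData(x) else as.data.frame(x)
  if (is(R, "LDMatrix")) R <- ldr(R)
  out <- list()
  for (i in seq_len(nrow(hits))) {
    sid <- sprintf("%d:%d", hits$chrom[i], hits$pos[i])
    others <- hits$index[-i]
    if (length(others) == 0L) {
      tab <- d
      tab$signal_id <- sid
      attr(tab, "dropped") <- 0L
      out[[sid]] <- tab
      next
    }
    Rss <- R[others, others, drop = FALSE]
    Rinv <- chol2inv(chol(Rss))
    A <- R[, others, drop = FALSE]
    w <- Rinv %*% d$z[others]
    num <- d$z - as.numeric(A %*% w)
    den2 <- 1 - rowSums((A %*% Rinv) * A)
    keep <- den2 >= 1 - r2Collinear
    keep[others] <- FALSE
    zc <- num / sqrt(pmax(den2, varFloor))
    tab <- d[keep, , drop = FALSE]
    tab$z <- zc[keep]
    tab$beta <- tab$z * tab$se
    tab$p <- .pFromZ(tab$z)
    tab$signal_id <- sid
    rownames(tab) <- NULL
    attr(tab, "dropped") <- sum(!keep)
    out[[sid]] <- tab
  }
  out
}

#' Clump, regionize, and isolate independent signals genome-wide
#'
#' Convenience wrapper running [greedyClump()], [defineRegions()], then
#' per region [stepwiseSelect()] and [isolateSignals()] with LD from the
#' panel.
#'
#' @param x genome-wide [SumStats-class] harmonized to `panel`.
#' @param panel [GenotypePanel-class] LD reference.
#' @param pThresh,r2Thresh,windowBp clumping parameters, see
#'   [greedyClump()].
#' @param padBp region padding, see [defineRegions()].
#' @param r2Collinear collinearity cutoff for selection/conditioning.
#' @return list with `clumps`, `regions`, `hits` (data.frame over all
#'   regions with a region column), and `signals` (named list of per-signal
#'   conditioned tables).
#' @export
findIndependentSignals <- function(x, panel, pThresh = 5e-8,
                                   r2Thresh = 0.1, windowBp = 3e6,
                                   padBp = 5e5, r2Collinear = 0.9) {
  clumps <- greedyClump(x, panel, pThresh, r2Thresh, windowBp)
  regions <- defineRegions(clumps, padBp)
  d <- sumstatsData(x)
  all_hits <- list()
  signals <- list()
  for (i in seq_len(nrow(regions))) {
    inreg <- which(d$chrom == regions$chrom[i] &
                     d$pos >= regions$start[i] & d$pos <= regions$end[i])
    sub <- d[inreg, , drop = FALSE]
    rownames(sub) <- NULL
    R <- ldCorrelation(panel, sub[, c("chrom", "pos", "a1", "a2")])
    hits <- stepwiseSelect(sub, R, pEntry = pThresh,
                           r2Collinear = r2Collinear)
    if (nrow(hits) == 0L) next
    hits$region <- i
    all_hits[[length(all_hits) + 1L]] <- hits
    signals <- c(signals, isolateSignals(sub, R, hits, r2Collinear))
  }
  list(clumps = clumps, regions = regions,
       hits = if (length(all_hits)) do.call(rbind, all_hits) else NULL,
       signals = signals)
}
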