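# internal helpers shared across modules

#' Canonical variant identifier strings
#'
#' @param x data.frame with chrom, pos, a1, a2 columns.
#' @return character vector "chrom:pos:a1:a2".
#' @export
variantId <- function(x) {
  paste(x$chrom, x$pos, x$a1, x$a2, sep = ":")
}

# position-only key (orientation-free matching against a panel)
.posId <- function(x) paste(x$chrom, x$pos, sep = ":")

# numerically stable log(sum(exp(x)))
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# DNA complement for strand-ambiguity checks
.complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.isStrandAmbiguous <- function(a1, a2) {
  a2 == .complement(a1)
}

#' Stabilize a correlation matrix to positive semi-definiteness
#'
#' Finite-sample correlation matrices of variant subsets can have tiny
#' negative eigenvalues; factorizations downstream must not fail. Adds
#' eps * I with eps = max(0, tol - lambda_min), then rescales back to unit
#' diagonal being unnecessary (the shift is uniform and small).
#'
#' @param r symmetric matrix.
#' @param tol smallest eigenvalue required after the shift.
#' @return list(r = stabilized matrix, shift = eps applied).
#' @keywords internal
.psdStabilize <- function(r, tol = 1e-8) {
  r <- (r + t(r)) / 2
  lam_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  shift <- max(0, tol - lam_min)
  if (shift > 0) {
    # shift then rescale so the diagonal stays exactly 1
    r <- (r + diag(shift, nrow(r))) / (1 + shift)
  }
  list(r = r, shift = shift)
}

# two-sided normal p-value from z, guarded against underflow to exactly 0
.pFromZ <- function(z) {
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  pmax(p, 1e-300)
}

# merge 1-based closed intervals on one chromosome; touching intervals merge
.mergeIntervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me + 1) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# derive a stream-specific 32-bit seed from a master seed
.deriveSeed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12497L) %% 2147483587L
}
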