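#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combines per-study effect sizes with weights 1/se^2:
#' beta = sum(beta_i/se_i^2) / sum(1/se_i^2), se = 1/sqrt(sum(1/se_i^2)).
#' A single study is returned unchanged.
#'
#' @param betas numeric vector of per-study effects.
#' @param ses numeric vector of per-study standard errors (> 0).
#' @return list(beta, se).
#' @export
ivwFixedEffects <- function(betas, ses) {
  if (length(betas) == 0L) stop("no studies supplied")
  if (length(betas) != length(ses)) stop("betas and ses differ in length")
  if (any(ses <= 0)) stop("all ses must be > 0")
  w <- 1 / ses^2
  list(beta = sum(w * betas) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Sample-size-weighted z-score meta-analysis
#'
#' Stouffer combination with sqrt(N) weights, preserving unit variance
#' under the null: z = sum(sqrt(N_i) z_i) / sqrt(sum(N_i)).
#'
#' @param zs numeric vector of per-study z-scores.
#' @param ns numeric vector of per-study effective sample sizes (> 0).
#' @return combined z (scalar).
#' @export
sqrtNZMeta <- function(zs, ns) {
  if (length(zs) == 0L) stop("no studies supplied")
  if (length(zs) != length(ns)) stop("zs and ns differ in length")
  if (any(ns <= 0)) stop("all ns must be > 0")
  sum(sqrt(ns) * zs) / sqrt(sum(ns))
}

#' Sample-size-weighted mean of per-study scores
#'
#' Weighted arithmetic mean with sqrt(N) weights (rank-preserving and
#' scale-stable, unlike the Stouffer denominator):
#' value = sum(sqrt(N_i) v_i) / sum(sqrt(N_i)).
#'
#' @param values numeric vector of per-study scores.
#' @param ns numeric vector of per-study effective sample sizes (> 0).
#' @return combined value (scalar).
#' @export
sqrtNWeightedMean <- function(values, ns) {
  if (length(values) == 0L) stop("no studies supplied")
  if (length(values) != length(ns)) stop("values and ns differ in length")
  if (any(ns <= 0)) stop("all ns must be > 0")
  w <- sqrt(ns)
  sum(w * values) / sum(w)
}

#' Variant-level fixed-effects meta-analysis of summary-statistics tables
#'
#' Matches records across studies by variant key (tables must already be
#' harmonized to a common panel orientation) and combines effects by
#' [ivwFixedEffects()] (default) or by the sample-size z scheme. Variants
#' present in only one study keep that study's statistics. Effective
#' sample sizes add.
#'
#' @param tables list of [SumStats-class] objects.
#' @param scheme "ivw" (effect-size weights) or "samplesize" (z-based;
#'   betas then reconstructed from the combined z and IVW se).
#' @param ancestry label for the combined table.
#' @return a [SumStats-class] with meta-analyzed records; af is the
#'   n_eff-weighted mean across contributing studies.
#' @export
metaAnalyze <- function(tables, scheme = c("ivw", "samplesize"),
                        ancestry = "META") {
  scheme <- match.arg(scheme)
  if (length(tables) == 0L) stop("no studies supplied")
  if (length(tables) == 1L) return(tables[[1]])
  dl <- lapply(tables, sumstatsData)
  ids <- lapply(dl, variantId)
  all_ids <- unique(unlist(ids, use.names = FALSE))
  k <- length(dl)
  idx <- vapply(seq_len(k), function(i) match(all_ids, ids[[i]]),
                integer(length(all_ids)))
  idx <- matrix(idx, ncol = k)

  get <- function(col) {
    m <- matrix(NA_real_, nrow = length(all_ids), ncol = k)
    for (i in seq_len(k)) {
      hit <- !is.na(idx[, i])
      m[hit, i] <- dl[[i]][[col]][idx[, i][hit]]
    }
    m
  }
  B <- get("beta"); S <- get("se"); N <- get("n_eff"); AF <- get("af")
  pres <- !is.na(B)
  W <- ifelse(pres, 1 / S^2, 0)
  sw <- rowSums(W)
  se_meta <- 1 / sqrt(sw)
  if (scheme == "ivw") {
    beta_meta <- rowSums(ifelse(pres, W * B, 0)) / sw
    z_meta <- beta_meta / se_meta
  } else {
    Z <- ifelse(pres, B / S, 0)
    Nw <- ifelse(pres, N, 0)
    z_meta <- rowSums(sqrt(Nw) * Z) / sqrt(rowSums(Nw))
    beta_meta <- z_meta * se_meta
  }
  n_tot <- rowSums(ifelse(pres, N, 0))
  af_meta <- rowSums(ifelse(pres, N * AF, 0)) / n_tot

  first <- apply(pres, 1, function(r) which(r)[1])
  nv <- length(all_ids)
  proto <- data.frame(chrom = integer(nv), pos = integer(nv),
                      a1 = character(nv), a2 = character(nv))
  for (i in seq_len(k)) {
    rows <- which(first == i)
    if (length(rows) > 0L)
      proto[rows, ] <- dl[[i]][idx[rows, i], c("chrom", "pos", "a1", "a2")]
  }
  d <- data.frame(proto, af = af_meta, beta = beta_meta, se = se_meta,
                  p = .pFromZ(z_meta), n_eff = n_tot,
                  stringsAsFactors = FALSE)
  makeSumStats(d, ancestry = ancestry,
               provenance = sprintf("%s meta-analysis of %d studies",
                                    scheme, k))
}
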