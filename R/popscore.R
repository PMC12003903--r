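#' Read a gene-by-feature matrix from TSV
#'
#' First column GENE_ID, remaining columns numeric features.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene ids as rownames.
#' @export
readFeatureMatrix <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  if (names(d)[1] != "GENE_ID") stop("first column must be GENE_ID")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$GENE_ID
  m
}

#' Write a gene-by-feature matrix to TSV
#'
#' @param X numeric matrix with gene ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(X, path) {
  out <- data.frame(GENE_ID = rownames(X), X, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Standardize feature columns
#'
#' Removes zero-variance columns (recorded in the "dropped" attribute) and
#' scales the rest to mean 0, sd 1; the per-feature mean and sd are kept
#' in the "center"/"scale" attributes.
#'
#' @param X numeric genes x features matrix.
#' @return standardized matrix with attributes center, scale, dropped.
#' @export
standardizeFeatures <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep],
              scale = sdv[keep])
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  attr(Xs, "center") <- mu[keep]
  attr(Xs, "scale") <- sdv[keep]
  attr(Xs, "dropped") <- colnames(X)[!keep]
  Xs
}

#' Marginal feature selection
#'
#' Keeps features whose univariate linear regression on the gene score
#' vector has p < alpha (correlation t-test, equivalent to the simple
#' regression slope test). Zero-variance features are excluded before
#' testing.
#'
#' @param y numeric gene score (z) vector.
#' @param X genes x features matrix, rows aligned with `y`.
#' @param alpha marginal selection threshold.
#' @return character vector of selected feature names.
#' @export
selectFeatures <- function(y, X, alpha = 0.05) {
  stopifnot(length(y) == nrow(X))
  n <- length(y)
  if (n < 3L) stop("need >= 3 genes")
  sdv <- apply(X, 2, sd)
  ok <- which(sdv > 0)
  r <- suppressWarnings(as.vector(cor(y, X[, ok, drop = FALSE])))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  colnames(X)[ok[p < alpha]]
}

# ridge solve: coefficients of (X'X + penalty I)^-1 X'y
.ridgeFit <- function(X, y, penalty) {
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) + penalty
  as.numeric(solve(XtX, crossprod(X, y)))
}

# generalized cross-validation on one fold via SVD
.ridgeGCV <- function(X, y, grid) {
  sv <- svd(X)
  d2 <- sv$d^2
  uty <- as.numeric(crossprod(sv$u, y))
  n <- length(y)
  scores <- vapply(grid, function(lam) {
    shrink <- d2 / (d2 + lam)
    fit <- sv$u %*% (shrink * uty)
    df <- sum(shrink)
    mean((y - fit)^2) / (1 - df / n)^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Leave-one-chromosome-out ridge scoring
#'
#' For each chromosome c, fits ridge regression of the gene score vector
#' on the (standardized) features using only genes NOT on c, then scores
#' the genes on c with the held-out fit. The intercept is the training
#' fold's mean score; coefficients solve (X'X + penalty I) b = X'y on
#' centered y. A gene's own association never informs its score.
#'
#' @param y numeric gene score vector.
#' @param X standardized genes x features matrix (selected features).
#' @param chromOfGene integer chromosome per gene, aligned with `y`.
#' @param penalty ridge penalty (raw, added to the Gram diagonal), or
#'   "gcv" to pick it per fold by generalized cross-validation over a
#'   log-spaced grid.
#' @param decorrelate optional function(y, X) -> list(y = , X = ) applied
#'   to each training fold before fitting (hook for gene-gene correlation
#'   whitening); held-out genes are scored on the untransformed features.
#' @return list(scores = held-out predictions aligned with `y`,
#'   coefficients = per-chromosome coefficient list, penalty =
#'   per-chromosome penalty used).
#' @export
ridgeLOCO <- function(y, X, chromOfGene, penalty = 100,
                      decorrelate = NULL) {
  stopifnot(length(y) == nrow(X), length(chromOfGene) == length(y))
  chroms <- sort(unique(chromOfGene))
  if (length(chroms) < 2L)
    stop("leave-one-chromosome-out needs >= 2 chromosomes")
  scores <- rep(NA_real_, length(y))
  coefs <- list()
  pens <- numeric(0)
  for (ch in chroms) {
    te <- which(chromOfGene == ch)
    tr <- which(chromOfGene != ch)
    ytr <- y[tr]; Xtr <- X[tr, , drop = FALSE]
    if (!is.null(decorrelate)) {
      dd <- decorrelate(ytr, Xtr)
      ytr <- dd$y; Xtr <- dd$X
    }
    mu <- mean(ytr)
    lam <- if (identical(penalty, "gcv"))
      .ridgeGCV(Xtr, ytr - mu, 10^seq(-1, 5, length.out = 25))
    else penalty
    b <- .ridgeFit(Xtr, ytr - mu, lam)
    scores[te] <- mu + as.numeric(X[te, , drop = FALSE] %*% b)
    coefs[[as.character(ch)]] <- b
    pens <- c(pens, lam)
  }
  list(scores = scores, coefficients = coefs, penalty = pens)
}

#' Genome-wide score percentiles
#'
#' percentile = (rank - 1) / (G - 1) with average ranks for ties, so the
#' genome-wide minimum maps to 0 and the maximum to 1.
#'
#' @param scores numeric vector.
#' @return percentiles in [0, 1].
#' @export
popsPercentile <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 genes")
  (rank(scores, ties.method = "average") - 1) / (length(scores) - 1)
}

#' Feature-based gene scores across ancestries
#'
#' Per ancestry: aligns the feature matrix to the ancestry's gene z
#' vector, standardizes, selects features marginally (p < `alpha`), and
#' computes leave-one-chromosome-out ridge scores. Per-ancestry raw
#' scores are then combined by the sqrt(N)-weighted mean and percentiles
#' are computed on the combined score.
#'
#' @param scoreList named list of [geneAssociation()] outputs (need
#'   gene_id, chrom, z), one per ancestry.
#' @param features raw genes x features matrix, rownames gene ids.
#' @param ns named per-ancestry effective sample sizes.
#' @param alpha marginal selection threshold.
#' @param penalty ridge penalty or "gcv", see [ridgeLOCO()].
#' @param decorrelate optional training-fold transform, see [ridgeLOCO()].
#' @return data.frame(gene_id, chrom, pops_<ancestry>..., pops_meta,
#'   pops_percentile); attribute "selected" holds the per-ancestry
#'   selected feature names.
#' @export
popsScore <- function(scoreList, features, ns, alpha = 0.05,
                      penalty = 100, decorrelate = NULL) {
  anc <- names(scoreList)
  stopifnot(!is.null(anc), all(anc %in% names(ns)))
  raw <- list()
  selected <- list()
  for (a in anc) {
    s <- scoreList[[a]]
    common <- intersect(s$gene_id, rownames(features))
    s <- s[match(common, s$gene_id), , drop = FALSE]
    Xs <- standardizeFeatures(features[common, , drop = FALSE])
    sel <- selectFeatures(s$z, Xs, alpha)
    selected[[a]] <- sel
    fit <- ridgeLOCO(s$z, Xs[, sel, drop = FALSE], s$chrom, penalty,
                     decorrelate)
    raw[[a]] <- data.frame(gene_id = s$gene_id, chrom = s$chrom,
                           score = fit$scores)
  }
  ids <- unique(unlist(lapply(raw, function(r) r$gene_id)))
  S <- sapply(raw, function(r) r$score[match(ids, r$gene_id)])
  S <- matrix(S, ncol = length(anc),
              dimnames = list(NULL, paste0("pops_", anc)))
  chrom <- rep(NA_integer_, length(ids))
  for (r in raw) chrom[match(r$gene_id, ids)] <- r$chrom
  W <- matrix(rep(sqrt(ns[anc]), each = length(ids)), ncol = length(anc))
  pres <- !is.na(S)
  meta <- rowSums(ifelse(pres, W * S, 0)) / rowSums(ifelse(pres, W, 0))
  out <- data.frame(gene_id = ids, chrom = chrom, S, pops_meta = meta,
                    pops_percentile = popsPercentile(meta),
                    row.names = NULL)
  attr(out, "selected") <- selected
  out
}
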