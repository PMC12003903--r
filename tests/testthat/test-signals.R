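# brute-force re-implementation of the greedy clumping definition,
# working directly on a full LD matrix
bruteClump <- function(d, R, pThresh, r2Thresh, flank) {
  assigned <- rep(FALSE, nrow(d))
  out <- list()
  repeat {
    sig <- which(!assigned & d$p < pThresh)
    if (length(sig) == 0L) break
    lead <- sig[order(d$p[sig], d$chrom[sig], d$pos[sig])][1]
    mem <- which(!assigned & d$chrom == d$chrom[lead] &
                   abs(d$pos - d$pos[lead]) <= flank &
                   (R[lead, ]^2 >= r2Thresh | seq_len(nrow(d)) == lead))
    assigned[mem] <- TRUE
    out[[length(out) + 1L]] <- list(lead = lead, members = sort(mem))
  }
  out
}

test_that("a lone significant variant forms a clump of itself", {
  vars <- data.frame(chrom = 1, pos = 100, a1 = "A", a2 = "G")
  panel <- makeTestPanel(50, vars, seed = 1)
  ss <- makeTestSumstats(chrom = 1, pos = 100, beta = 0.65, se = 0.1)
  cl <- greedyClump(ss, panel)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$lead$pos, 100L)
  expect_equal(nrow(cl[[1]]$members), 1L)
  # no significant variants -> empty result
  ss0 <- makeTestSumstats(chrom = 1, pos = 100, beta = 0.1, se = 0.1)
  expect_length(greedyClump(ss0, panel), 0L)
})

test_that("LD-linked neighbours join the stronger lead; distant peaks split", {
  vars <- data.frame(chrom = 1, pos = c(100e3, 150e3, 5e6), a1 = "A",
                     a2 = "G")
  set.seed(4)
  x1 <- rbinom(4000, 2, 0.4)
  x2 <- ifelse(runif(4000) < 0.72, x1, rbinom(4000, 2, 0.4))  # r2 ~ 0.5
  x3 <- rbinom(4000, 2, 0.4)
  panel <- makeGenotypePanel(cbind(x1, x2, x3), vars, rep("EUR", 4000))
  ss <- makeTestSumstats(chrom = 1, pos = vars$pos,
                         beta = c(0.64, 0.60, 0.60), se = 0.1,
                         p = c(1e-10, 1e-9, 1e-9))
  cl <- greedyClump(ss, panel)
  expect_length(cl, 2L)
  expect_equal(sort(vapply(cl, function(x) x$lead$pos, integer(1))),
               c(100000L, 5000000L))
  expect_equal(cl[[1]]$members$pos, c(100000L, 150000L))
})

test_that("greedy clumping matches the brute-force evaluator on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- 200
    chrom <- sort(sample(1:2, m, replace = TRUE))
    pos <- unlist(tapply(seq_len(m), chrom, function(i)
      sort(sample.int(4e6, length(i)))))
    vars <- data.frame(chrom = chrom, pos = pos, a1 = "A", a2 = "G")
    dos <- do.call(cbind, lapply(split(seq_len(m), chrom), function(i)
      simulateGenotypes(150, length(i), rho = 0.8, seed = seed + 1000)))
    panel <- makeGenotypePanel(dos, vars, rep("EUR", 150))
    z <- rnorm(m, sd = 3)
    ss <- makeTestSumstats(chrom = chrom, pos = pos, beta = z * 0.1,
                           se = 0.1)
    d <- sumstatsData(ss)
    R <- suppressWarnings(cor(dosages(panel)[,
      match(variantId(d), variantId(variantKeys(panel)))]))
    R[is.na(R)] <- 0
    expected <- bruteClump(d, R, 5e-8, 0.1, 1.5e6)
    got <- greedyClump(ss, panel)
    expect_length(got, length(expected))
    for (k in seq_along(expected)) {
      expect_equal(got[[k]]$lead$pos, d$pos[expected[[k]]$lead])
      expect_equal(sort(got[[k]]$members$pos),
                   sort(d$pos[expected[[k]]$members]))
    }
  }
})

test_that("regions are padded, clamped and merged", {
  mkclump <- function(chrom, lo, hi)
    list(chrom = chrom, span = c(lo, hi))
  r <- defineRegions(list(mkclump(1L, 1e6, 1.05e6)))
  expect_equal(c(r$start, r$end), c(5e5, 1.55e6))
  # padded intervals overlapping by 1 bp merge into one region
  r2 <- defineRegions(list(mkclump(1L, 1e6, 1.05e6),
                           mkclump(1L, 2.05e6, 2.1e6)))
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(5e5, 2.6e6))
  # clamp at chromosome start
  r3 <- defineRegions(list(mkclump(2L, 2e5, 2.1e5)))
  expect_equal(c(r3$start, r3$end), c(1, 7.1e5))
  # different chromosomes never merge
  r4 <- defineRegions(list(mkclump(1L, 1e6, 1.1e6),
                           mkclump(2L, 1e6, 1.1e6)))
  expect_equal(nrow(r4), 2L)
})

test_that("conditional z follows the closed form and its edge cases", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  z <- c(6, 6)
  expect_equal(conditionalZ(z, R, integer(0), 1), 6)
  expect_equal(conditionalZ(z, R, 2, 1), 3 / sqrt(0.75), tolerance = 1e-9)
  Rp <- matrix(c(1, 1, 1, 1), 2)   # perfect LD
  expect_error(conditionalZ(z, Rp, 2, 1), "collinear")
  # uncorrelated selected hit leaves the marginal z unchanged
  R0 <- diag(2)
  expect_equal(conditionalZ(z, R0, 2, 1), 6)
})

test_that("conditional z equals explicit multiple regression on genotypes", {
  for (seed in 1:10) {
    n <- 300; m <- 6
    X <- simulateGenotypes(n, m, rho = 0.6, maf = 0.35, seed = seed)
    if (any(apply(X, 2, sd) == 0)) next
    set.seed(seed + 500)
    y <- X[, 2] * 0.2 + rnorm(n)
    Xs <- scale(X); ys <- as.numeric(scale(y))
    R <- cor(X)
    zmarg <- sqrt(n - 1) * as.numeric(cor(X, y))
    S <- c(2, 5); f <- 3
    # oracle: regression of y on the selected + focal genotypes, unit
    # residual variance (summary-statistic convention)
    Xr <- Xs[, c(S, f)]
    G <- solve(crossprod(Xr))
    bhat <- as.numeric(G %*% crossprod(Xr, ys))
    z_oracle <- bhat[3] / sqrt(G[3, 3])
    expect_equal(conditionalZ(zmarg, R, S, f), z_oracle,
                 tolerance = 1e-6)
  }
})

test_that("stepwise selection recovers planted signals", {
  m <- 50; N <- 2e4
  R <- ar1Matrix(m, 0.9)
  L <- chol(R)
  maf <- rep(0.3, m)
  run_region <- function(b, seed) {
    ss <- simulateSumstats(R, b, N, maf, seed = seed,
                           keys = data.frame(chrom = 1,
                                             pos = 1000 * seq_len(m),
                                             a1 = "A", a2 = "G"))
    stepwiseSelect(sumstatsData(ss), R)
  }
  # one planted causal variant at sqrt(N) b = 8 -> exactly one hit, and
  # nothing stays significant after conditioning on it
  b <- rep(0, m); b[25] <- 8 / sqrt(N)
  for (seed in c(2, 3, 5)) {
    hits <- run_region(b, seed)
    expect_equal(nrow(hits), 1L)
    ss <- simulateSumstats(R, b, N, maf, seed = seed,
                           keys = data.frame(chrom = 1,
                                             pos = 1000 * seq_len(m),
                                             a1 = "A", a2 = "G"))
    z <- sumstatsData(ss)$z
    others <- setdiff(seq_len(m), hits$index)
    pc <- vapply(others, function(j)
      tryCatch(2 * pnorm(abs(conditionalZ(z, R, hits$index, j)),
                         lower.tail = FALSE),
               error = function(e) 1), numeric(1))
    expect_gte(min(pc), 5e-8)
  }
  # null region: no hits when nothing reaches significance
  hits0 <- run_region(rep(0, m), seed = 7)
  expect_equal(nrow(hits0), 0L)
  # two nearly independent causal variants -> two hits
  b2 <- rep(0, m); b2[c(5, 45)] <- 8 / sqrt(N)   # rho^40 ~ 0.015
  for (seed in c(11, 13)) {
    hits2 <- run_region(b2, seed)
    expect_equal(nrow(hits2), 2L)
  }
})

test_that("stepwise selection is invariant to row order", {
  m <- 30; N <- 2e4
  R <- ar1Matrix(m, 0.85)
  b <- rep(0, m); b[c(4, 26)] <- 9 / sqrt(N)
  keys <- data.frame(chrom = 1, pos = 1000 * seq_len(m), a1 = "A",
                     a2 = "G")
  ss <- simulateSumstats(R, b, N, rep(0.3, m), seed = 21, keys = keys)
  d <- sumstatsData(ss)
  set.seed(22)
  perm <- sample.int(m)
  h1 <- stepwiseSelect(d, R)
  h2 <- stepwiseSelect(d[perm, ], R[perm, perm])
  expect_equal(h1$pos, sort(h2$pos))
  expect_equal(h1$joint_z[order(h1$pos)],
               h2$joint_z[order(h2$pos)], tolerance = 1e-10)
})

test_that("leave-one-hit-out conditioning isolates each signal", {
  m <- 40; N <- 2e4
  R <- ar1Matrix(m, 0.9)
  keys <- data.frame(chrom = 1, pos = 1000 * seq_len(m), a1 = "A",
                     a2 = "G")
  b <- rep(0, m); b[c(5, 35)] <- 9 / sqrt(N)
  ss <- simulateSumstats(R, b, N, rep(0.3, m), seed = 31, keys = keys)
  d <- sumstatsData(ss)
  hits <- stepwiseSelect(d, R)
  expect_equal(nrow(hits), 2L)
  iso <- isolateSignals(d, R, hits)
  expect_length(iso, 2L)
  sigA <- iso[[1]]
  # the other hit's neighbourhood is explained away in signal A's table
  nearB <- which(abs(sigA$pos - d$pos[hits$index[2]]) <= 2000)
  expect_lt(max(abs(sigA$z[nearB])), 5)
  # but the own hit's signal remains genome-wide significant
  expect_lt(sigA$p[sigA$pos == d$pos[hits$index[1]]], 5e-8)
  # single hit: conditioned table equals the input verbatim
  b1 <- rep(0, m); b1[20] <- 9 / sqrt(N)
  ss1 <- simulateSumstats(R, b1, N, rep(0.3, m), seed = 32, keys = keys)
  d1 <- sumstatsData(ss1)
  h1 <- stepwiseSelect(d1, R)
  expect_equal(nrow(h1), 1L)
  iso1 <- isolateSignals(d1, R, h1)[[1]]
  expect_equal(iso1[, names(d1)], d1)
})
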