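test_that("panel simulation controls adjacent-variant LD through rho", {
  spec0 <- fixtureSpec(nBlocks = 2L, nHard = 0L, variantsPerBlock = 40L,
                       nSamples = c(EUR = 5000L, EAS = 100L),
                       rho = c(EUR = 0, EAS = 0.8), seed = 3)
  lay0 <- fixtureLayout(spec0)
  p0 <- simulatePanel(spec0, lay0, "EUR")
  adjr <- function(panel, lay) {
    v <- lay$variants
    unlist(lapply(unique(v$block), function(b) {
      idx <- which(v$block == b)
      d <- dosages(panel)[, idx]
      vapply(seq_len(length(idx) - 1L), function(j)
        suppressWarnings(cor(d[, j], d[, j + 1])), numeric(1))
    }))
  }
  expect_lt(mean(abs(adjr(p0, lay0)), na.rm = TRUE), 0.05)

  spec9 <- fixtureSpec(nBlocks = 2L, nHard = 0L, variantsPerBlock = 40L,
                       nSamples = c(EUR = 5000L, EAS = 100L),
                       rho = c(EUR = 0.95, EAS = 0.8), seed = 3)
  p9 <- simulatePanel(spec9, fixtureLayout(spec9), "EUR")
  expect_gt(mean(adjr(p9, fixtureLayout(spec9))), 0.6)

  # determinism: same seed, same panel
  p9b <- simulatePanel(spec9, fixtureLayout(spec9), "EUR")
  expect_identical(dosages(p9), dosages(p9b))
})

test_that("simulated summary statistics follow the planted mean structure", {
  # null variant: mean ~ 0, variance ~ 1 over replicate draws
  R1 <- matrix(1, 1, 1)
  keys1 <- data.frame(chrom = 1, pos = 100, a1 = "A", a2 = "G")
  z <- vapply(1:10000, function(i)
    sumstatsData(simulateSumstats(R1, 0, 2e4, 0.3, seed = i,
                                  keys = keys1))$z, numeric(1))
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.05)

  # causal variant at sqrt(N) b = 8 with a neighbour at r = 0.5
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  keys <- data.frame(chrom = 1, pos = c(100, 200), a1 = "A", a2 = "G")
  N <- 2e4
  zz <- vapply(1:3000, function(i)
    sumstatsData(simulateSumstats(R, c(8 / sqrt(N), 0), N, c(0.3, 0.3),
                                  seed = 10000 + i, keys = keys))$z,
    numeric(2))
  expect_equal(mean(zz[1, ]), 8, tolerance = 0.1)
  expect_equal(mean(zz[2, ]), 4, tolerance = 0.1)

  # determinism
  s1 <- simulateSumstats(R, c(0, 0), N, c(0.3, 0.3), seed = 5,
                         keys = keys)
  s2 <- simulateSumstats(R, c(0, 0), N, c(0.3, 0.3), seed = 5,
                         keys = keys)
  expect_identical(sumstatsData(s1), sumstatsData(s2))
})

# analytic dosage correlation implied by the Gaussian-copula haplotype
# model: correlation of indicators 1(Z > t) with latent correlation rho
copulaDosageR <- function(rho, maf1, maf2) {
  t1 <- qnorm(1 - maf1); t2 <- qnorm(1 - maf2)
  p11 <- integrate(function(x)
    dnorm(x) * pnorm((rho * x - t2) / sqrt(1 - rho^2)),
    t1, Inf, rel.tol = 1e-10)$value
  (p11 - maf1 * maf2) /
    sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

test_that("panel LD converges to the model-implied AR(1) correlation", {
  spec <- fixtureSpec(nBlocks = 1L, nHard = 0L, variantsPerBlock = 15L,
                      nSamples = c(EUR = 20000L, EAS = 100L),
                      rho = c(EUR = 0.9, EAS = 0.8), seed = 6)
  lay <- fixtureLayout(spec)
  panel <- simulatePanel(spec, lay, "EUR")
  R <- ldr(ldCorrelation(panel, stabilize = FALSE))
  v <- lay$variants
  adj <- R[cbind(1:14, 2:15)]
  expected <- vapply(1:14, function(j)
    copulaDosageR(0.9, v$maf[j], v$maf[j + 1]), numeric(1))
  expect_lt(max(abs(adj - expected)), 0.05)
  # two steps apart follows the AR(1) latent rho^2
  expected2 <- vapply(1:13, function(j)
    copulaDosageR(0.81, v$maf[j], v$maf[j + 2]), numeric(1))
  expect_lt(max(abs(R[cbind(1:13, 3:15)] - expected2)), 0.05)
})

test_that("pathway features are recoverable and noise stays at the null rate", {
  spec <- fixtureSpec(seed = 4)
  lay <- fixtureLayout(spec)
  gids <- S4Vectors::mcols(lay$genes)$gene_id
  causal <- unique(lay$truth$causal_gene)
  X <- simulateGeneFeatures(gids, causal, spec)
  # a z-vector strongly elevated at causal genes recovers the pathways
  set.seed(40)
  y <- rnorm(length(gids)) + 8 * (gids %in% causal)
  sel <- selectFeatures(y, standardizeFeatures(X), alpha = 0.05)
  expect_gte(sum(grepl("^PATHWAY_", sel)), 3L)
  # with a null y, selected noise features stay within the binomial band
  set.seed(41)
  y0 <- rnorm(length(gids))
  sel0 <- selectFeatures(y0, standardizeFeatures(X), alpha = 0.05)
  nn <- sum(grepl("^NOISE_", sel0))
  expect_lte(nn, qbinom(0.999, spec$nNoiseFeatures, 0.05))
  # determinism
  expect_identical(X, simulateGeneFeatures(gids, causal, spec))
})

test_that("a fixture bundle is reproducible and writes every input format", {
  spec <- fixtureSpec(nBlocks = 4L, nHard = 1L, nChrom = 4L,
                      nNoiseFeatures = 50L,
                      nSamples = c(EUR = 150L, EAS = 80L), seed = 9)
  fx1 <- makeFixture(spec)
  fx2 <- makeFixture(spec)
  expect_identical(sumstatsData(fx1$sumstats$EUR),
                   sumstatsData(fx2$sumstats$EUR))
  expect_identical(dosages(fx1$panels$EAS), dosages(fx2$panels$EAS))
  expect_identical(fx1$features, fx2$features)
  # every causal variant lies inside its causal gene's body
  g <- fx1$genes
  for (i in seq_len(nrow(fx1$truth))) {
    gi <- g[S4Vectors::mcols(g)$gene_id == fx1$truth$causal_gene[i]]
    expect_gte(fx1$truth$causal_pos[i], GenomicRanges::start(gi))
    expect_lte(fx1$truth$causal_pos[i], GenomicRanges::end(gi))
  }
  # hard-block causal variants are flagged non-synonymous
  hard <- fx1$truth[fx1$truth$hard, ]
  ns_ids <- variantId(fx1$nonsyn)
  expect_true(all(sprintf("%d:%d:A:G", hard$chrom, hard$causal_pos) %in%
                    ns_ids))
  dir <- withr::local_tempdir()
  writeFixture(fx1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("sumstats_EUR.tsv", "sumstats_EAS.tsv", "panel_EUR.tsv",
      "panel_EAS.tsv", "genes.tsv", "features.tsv", "nonsyn.tsv",
      "truth_table.tsv", "fixture_manifest.json")))))
  # the written sumstats reload to the same table
  back <- readSumstats(file.path(dir, "sumstats_EUR.tsv"),
                       ancestry = "EUR")
  expect_equal(sumstatsData(back), sumstatsData(fx1$sumstats$EUR),
               tolerance = 1e-12)
})
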