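test_that("mixed panel reproduces the two-ancestry worked example", {
  vars <- data.frame(chrom = 1, pos = c(100, 200), a1 = "A", a2 = "G")
  eas <- makeTestPanel(538, vars, ancestry = "EAS", seed = 1)
  eur <- makeTestPanel(16860, vars, ancestry = "EUR", seed = 2)
  share <- c(EAS = 15886, EUR = 127626) / (15886 + 127626)
  mix <- buildMixedPanel(list(EAS = eas, EUR = eur), share, seed = 3)
  expect_equal(unname(mix$counts["EAS"]), 538L)
  expect_equal(unname(mix$counts["EUR"]), 4322L)
  expect_equal(sum(sampleAncestry(mix$panel) == "EUR"), 4322L)
})

test_that("equal shares with equal availability keep everyone", {
  vars <- data.frame(chrom = 1, pos = 100, a1 = "A", a2 = "G")
  p1 <- makeTestPanel(100, vars, ancestry = "A", seed = 1)
  p2 <- makeTestPanel(100, vars, ancestry = "B", seed = 2)
  mix <- buildMixedPanel(list(A = p1, B = p2), c(A = 0.5, B = 0.5))
  expect_equal(unname(mix$counts), c(100L, 100L))
})

test_that("an unattainable share names the ancestry and the attainable share", {
  vars <- data.frame(chrom = 1, pos = 100, a1 = "A", a2 = "G")
  eas <- makeTestPanel(538, vars, ancestry = "EAS", seed = 1)
  eur <- makeTestPanel(100, vars, ancestry = "EUR", seed = 2)
  expect_error(
    buildMixedPanel(list(EAS = eas, EUR = eur),
                    c(EAS = 0.01, EUR = 0.99), includeAll = "EAS"),
    "EUR")
})

test_that("LD correlation honours its shape and diagonal contracts", {
  vars <- data.frame(chrom = 1, pos = c(100, 200, 300), a1 = "A",
                     a2 = "G")
  set.seed(7)
  dos <- matrix(rbinom(50 * 3, 2, 0.4), 50, 3)
  dos[, 3] <- dos[, 1]                      # duplicated column: r = 1
  panel <- makeGenotypePanel(dos, vars, rep("EUR", 50))
  ld <- ldCorrelation(panel, stabilize = FALSE)
  r <- ldr(ld)
  expect_equal(dim(r), c(3L, 3L))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r, t(r))
  expect_equal(r[1, 3], 1)
})

test_that("independent variants show near-zero LD at large n", {
  vars <- data.frame(chrom = 1, pos = c(100, 200), a1 = "A", a2 = "G")
  panel <- makeTestPanel(10000, vars, seed = 11)
  r <- ldr(ldCorrelation(panel))
  expect_lt(abs(r[1, 2]), 0.05)
})

test_that("LD is invariant to sample order and PSD after stabilization", {
  m <- 12
  vars <- data.frame(chrom = 1, pos = 100 * seq_len(m), a1 = "A",
                     a2 = "G")
  dos <- simulateGenotypes(40, m, rho = 0.9, seed = 5)
  panel <- makeGenotypePanel(dos, vars, rep("EUR", 40))
  set.seed(9)
  perm <- sample.int(40)
  panel2 <- makeGenotypePanel(dos[perm, ], vars, rep("EUR", 40))
  expect_equal(ldr(ldCorrelation(panel)), ldr(ldCorrelation(panel2)))
  lam <- eigen(ldr(ldCorrelation(panel)), symmetric = TRUE,
               only.values = TRUE)$values
  expect_gte(min(lam), -1e-10)
})

test_that("monomorphic columns among requested keys raise an error", {
  vars <- data.frame(chrom = 1, pos = c(100, 200), a1 = "A", a2 = "G")
  dos <- cbind(rbinom(20, 2, 0.5), rep(0, 20))
  panel <- makeGenotypePanel(dos, vars, rep("EUR", 20))
  expect_error(ldCorrelation(panel), "monomorphic")
})

test_that("PLINK-1 binary trio roundtrips dosages, keys and ancestry", {
  m <- 7; n <- 13          # n not divisible by 4 exercises byte padding
  vars <- data.frame(chrom = rep(c(1L, 2L), c(4, 3)),
                     pos = 100L * seq_len(m),
                     a1 = rep(c("A", "C"), length.out = m),
                     a2 = rep(c("G", "T"), length.out = m))
  set.seed(3)
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  panel <- makeGenotypePanel(dos, vars, rep(c("EUR", "EAS"),
                                            length.out = n))
  prefix <- withr::local_tempfile()
  writePlinkPanel(panel, prefix)
  back <- readPlinkPanel(prefix)
  expect_equal(unname(dosages(back)), unname(dosages(panel)))
  expect_equal(variantKeys(back), variantKeys(panel))
  expect_equal(sampleAncestry(back), sampleAncestry(panel))
})

test_that("dosage TSV roundtrips a panel", {
  vars <- data.frame(chrom = 1, pos = c(100, 200), a1 = "A", a2 = "G")
  panel <- makeTestPanel(9, vars, seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDosageTSV(panel, path)
  back <- readDosageTSV(path)
  expect_equal(unname(dosages(back)), unname(dosages(panel)))
  expect_equal(variantKeys(back), variantKeys(panel))
})
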