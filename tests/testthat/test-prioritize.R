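mkGenes <- function(...) {
  d <- data.frame(...)
  makeGeneModels(data.frame(gene_id = d$gene_id, chrom = 1,
                            start = d$start, end = d$end, strand = "+"))
}

test_that("locus membership uses closed-interval overlap", {
  genes <- mkGenes(gene_id = c("A", "B", "C"),
                   start = c(0.9e6, 1.2e6, 1.7e6),
                   end = c(1.1e6, 1.3e6, 1.8e6))
  locus <- GenomicRanges::GRanges("1", IRanges::IRanges(1.0e6, 1.6e6))
  gl <- genesInLocus(locus, genes)
  expect_equal(sort(S4Vectors::mcols(gl$genes)$gene_id), c("A", "B"))
  expect_equal(gl$count, 2L)
  # empty gene set
  empty <- genesInLocus(locus, genes[0])
  expect_equal(empty$count, 0L)
  # gene abutting the locus end is included
  genes2 <- mkGenes(gene_id = "D", start = 1.6e6, end = 1.65e6)
  expect_equal(genesInLocus(locus, genes2)$count, 1L)
})

test_that("gene-to-center distance is zero inside, else edge distance in kb", {
  expect_equal(geneCsDistance(1e6, 1.1e6, 1.05e6), 0)
  expect_equal(geneCsDistance(1e6, 1.1e6, 1.15e6), 50)
  expect_equal(geneCsDistance(1e6, 1.1e6, 0.95e6), 50)
  expect_error(geneCsDistance(1e6, 1.1e6, 1.05e6, geneChrom = 1,
                              centerChrom = 2), "chromosome")
})

test_that("the per-locus rule selects top-score-and-nearest or nonsyn genes", {
  # single gene: trivially selected by rule A
  one <- data.frame(gene_id = "A", distance_kb = 10, pops = 0.1,
                    nonsyn_pip = 0)
  expect_equal(prioritizeLocus(one)$selected, "A")
  # top score and nearest disagree, no nonsyn: nothing selected
  two <- data.frame(gene_id = c("A", "B"), distance_kb = c(0, 50),
                    pops = c(0.1, 0.9), nonsyn_pip = 0)
  expect_true(is.na(prioritizeLocus(two)$selected))
  # rule B overrides a rule-A gene (conflict rule)
  conf <- data.frame(gene_id = c("X", "Y"), distance_kb = c(0, 80),
                     pops = c(0.9, 0.1), nonsyn_pip = c(0, 0.6))
  expect_equal(prioritizeLocus(conf)$selected, "Y")
  # ties in the argmax void rule A
  tie <- data.frame(gene_id = c("A", "B"), distance_kb = c(0, 50),
                    pops = c(0.5, 0.5), nonsyn_pip = 0)
  expect_true(is.na(prioritizeLocus(tie)$selected))
  # strict threshold at 50% PIP
  at <- data.frame(gene_id = "A", distance_kb = 99, pops = NA,
                   nonsyn_pip = 0.5)
  expect_false(isTRUE(prioritizeLocus(at)$flags$flag_nonsyn))
})

test_that("selection matches a brute-force rule evaluator on enumerated cases", {
  bruteRule <- function(cand, thr = 0.5) {
    nb <- cand$gene_id[cand$nonsyn_pip > thr]
    if (length(nb) >= 1L) return(nb[1])
    ok <- !is.na(cand$pops)
    if (!any(ok)) return(NA_character_)
    top <- cand$gene_id[ok][cand$pops[ok] == max(cand$pops[ok])]
    near <- cand$gene_id[cand$distance_kb == min(cand$distance_kb)]
    if (length(top) == 1L && length(near) == 1L && top == near) top
    else NA_character_
  }
  popsv <- c(0.1, 0.5, 0.9)
  dists <- c(0, 20, 20)
  pipsv <- c(0, 0.6)
  cases <- expand.grid(p1 = popsv, p2 = popsv, p3 = popsv,
                       d1 = dists, d2 = dists, d3 = dists,
                       ns2 = pipsv)
  set.seed(15)
  cases <- cases[sample(nrow(cases), 250), ]
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    cand <- data.frame(gene_id = c("A", "B", "C"),
                       distance_kb = c(cc$d1, cc$d2, cc$d3),
                       pops = c(cc$p1, cc$p2, cc$p3),
                       nonsyn_pip = c(0, cc$ns2, 0))
    got <- prioritizeLocus(cand)$selected
    expect_identical(got, bruteRule(cand))
    # order invariance
    perm <- c(3, 1, 2)
    got2 <- prioritizeLocus(cand[perm, ])$selected
    expect_identical(got2, got)
  }
})

test_that("full-locus prioritization flags candidates and respects nonsyn PIP", {
  genes <- mkGenes(gene_id = c("A", "B"),
                   start = c(0.95e6, 1.2e6), end = c(1.1e6, 1.35e6))
  tab <- data.frame(chrom = 1L, pos = c(1.0e6, 1.25e6), a1 = "A",
                    a2 = "G", z = c(9, 5), se = 0.05,
                    signal_id = "1:1000000")
  cs <- fineMapSignal(tab)
  pops <- data.frame(gene_id = c("A", "B"), pops_meta = c(2, 1),
                     pops_percentile = c(1, 0))
  gz <- data.frame(gene_id = c("A", "B"), z_meta = c(5, 1))
  # without nonsyn info rule A selects A (top score, nearest)
  res <- prioritizeGenes(list(cs), genes, pops, gz)
  t <- prioritizationTable(res)
  expect_equal(t$gene_id[t$selected], "A")
  expect_equal(unique(t$n_genes_in_locus), 2L)
  # flag the second variant as non-synonymous: it sits in B, but its PIP
  # is small, so the selection is unchanged
  ns <- data.frame(chrom = 1L, pos = 1.25e6, a1 = "A", a2 = "G")
  res2 <- prioritizeGenes(list(cs), genes, pops, gz, nonsyn = ns)
  t2 <- prioritizationTable(res2)
  expect_equal(t2$gene_id[t2$selected], "A")
  expect_true(all(t2$nonsyn_pip <= 1))
})

test_that("BED-like exports convert between closed and half-open coordinates", {
  d <- data.frame(chrom = c(1L, 2L), start = c(1, 501), end = c(100, 900))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeBedTSV(d, path)
  raw <- read.delim(path)
  expect_equal(raw$START, c(0, 500))
  expect_equal(raw$END, c(100, 900))
  back <- readBedTSV(path)
  expect_equal(back[, c("chrom", "start", "end")], d)
})
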