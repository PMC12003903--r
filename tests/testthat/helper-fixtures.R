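# shared helpers for building tiny in-code fixtures

# AR(1) correlation matrix
ar1Matrix <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# a SumStats built from minimal pieces; p derived from z unless given
makeTestSumstats <- function(chrom, pos, a1 = "A", a2 = "G", af = 0.3,
                             beta = 0.1, se = 0.05, p = NULL,
                             n_eff = 1e4, ancestry = "EUR") {
  n <- length(pos)
  d <- data.frame(chrom = chrom, pos = pos,
                  a1 = rep_len(a1, n), a2 = rep_len(a2, n),
                  af = rep_len(af, n), beta = rep_len(beta, n),
                  se = rep_len(se, n), n_eff = rep_len(n_eff, n))
  d$p <- if (is.null(p)) 2 * pnorm(abs(d$beta / d$se), lower.tail = FALSE)
         else rep_len(p, n)
  makeSumStats(d, ancestry = ancestry)
}

# a small panel with independent binomial dosages (no LD structure)
makeTestPanel <- function(nSamples, variants, ancestry = "EUR",
                          seed = 42, maf = 0.3) {
  set.seed(seed)
  m <- nrow(variants)
  dos <- matrix(rbinom(nSamples * m, 2, maf), nrow = nSamples)
  makeGenotypePanel(dos, variants, rep(ancestry, nSamples))
}

# simulate raw genotypes with AR(1) LD via the Gaussian copula
simulateGenotypes <- function(n, m, rho, maf = 0.3, seed = 1) {
  set.seed(seed)
  L <- chol(ar1Matrix(m, rho))
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m) %*% L
    (z > qnorm(1 - maf)) + 0
  }
  hap() + hap()
}
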