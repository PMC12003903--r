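---
title: "From GWAS summary statistics to prioritized genes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS summary statistics to prioritized genes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signal2gene)
```

# Overview

`signal2gene` turns per-ancestry GWAS summary statistics and an LD
reference panel into a per-locus table of candidate genes with a single
nominated gene per locus. The chain is:

1. harmonization and allele-frequency quality control against the panel;
2. inverse-variance fixed-effects meta-analysis across ancestries;
3. LD clumping, region construction, and stepwise conditional-and-joint
   selection of independent signals;
4. single-causal-variant fine-mapping of each isolated signal into a 95%
   credible set, with a PIP-weighted center and a padded locus;
5. SNP-wise mean gene-level association with an LD-aware null;
6. genome-wide feature-based gene scoring by leave-one-chromosome-out
   ridge regression;
7. a per-locus decision rule combining the top feature score, proximity
   to the credible-set center, and non-synonymous credible-set variants.

A synthetic-data module generates every input with known ground truth, so
the full chain can be exercised and validated offline.

# Statistical models

## Harmonization and quality control

Records are matched to the panel by position. A record whose allele pair
equals the panel's in swapped order has its effect sign flipped and its
frequency complemented; strand-ambiguous records (A/T, C/G) with effect
allele frequency in the open window (0.4, 0.6) cannot be oriented and
are dropped (window configurable). Frequency QC then removes records
whose frequency differs from the panel's by more than 0.1 absolute,
then records whose symmetric fold change exceeds 12. All three
thresholds are strict inequalities; the fold rule uses the symmetric
max-ratio of the harmonized effect allele so it is orientation
invariant. Deduplication keeps the record with the smaller p-value. The
gene analysis additionally requires minor-allele frequency strictly
above 1%.

## Meta-analysis

Variant effects combine by inverse-variance weights,
$\hat\beta = \sum_i \beta_i/se_i^2 \,/\, \sum_i 1/se_i^2$,
$se = (\sum_i 1/se_i^2)^{-1/2}$; a sample-size z-based scheme is
available as a configuration option. Gene-level z-scores combine by the
unit-variance-preserving Stouffer rule with $\sqrt{N}$ weights,
$z = \sum_i \sqrt{N_i} z_i / \sqrt{\sum_i N_i}$. Feature-based gene
scores are not z-scores, so they combine by a $\sqrt{N}$-weighted
arithmetic mean, which is rank-preserving and scale-stable; the
Stouffer denominator would inflate the scale of a k-study combination
by $\sqrt{k}$, which is undesirable for a quantity whose genome-wide
ranks feed the selection rule. Effective sample sizes are taken as
given in the input tables and never recomputed from case/control
counts, because published effective sizes often come from per-cohort
summation that cannot be reproduced from the marginal totals.

## Independent signals

Clumping is the standard greedy procedure: the most significant
unassigned variant (p < 5e-8) becomes a lead; every unassigned variant
within half the 3 Mb window whose $r^2$ with the lead is at least 0.1
joins its clump. Members are not further p-filtered (configurable).
Ties in p break by (chromosome, position) for determinism. Clump spans
padded by 500 kb merge transitively into regions.

Within a region, conditional analysis works entirely on the
standardized (per-SD) scale through z-statistics: for focal variant $f$
and selected set $S$,

$$z_{f|S} = \frac{z_f - R_{fS} R_{SS}^{-1} z_S}
                 {\sqrt{1 - R_{fS} R_{SS}^{-1} R_{Sf}}}.$$

This is algebraically the z-statistic of $f$ in a joint regression on
the raw genotypes with unit residual variance, which the test suite
verifies against explicit multiple regression on simulated genotypes.
Working per-SD avoids the allele-frequency and phenotypic-variance
bookkeeping of frequency-scale conditional-and-joint tools; it is a
deliberate simplification that is equivalent at the z level. Forward
selection adds the candidate with the smallest conditional p while it
stays below 5e-8, skipping candidates with $r^2 > 0.9$ to any selected
variant (the conventional collinearity cutoff, configurable; the
conditional variance is floored at 1e-6). Joint statistics over the
selected set are $b = R_{SS}^{-1} z_S$ with variance $R_{SS}^{-1}$, so
$z_j = b_j / \sqrt{(R_{SS}^{-1})_{jj}}$; hits with joint p above 5e-8
are pruned worst-first with refitting. Each retained hit's signal is
isolated by conditioning every region variant on the *other* hits
(leave-one-hit-out); with a single hit the marginal statistics pass
through unchanged.

## Fine-mapping

Each isolated signal is fine-mapped under the exactly-one-causal-variant
model with Wakefield approximate Bayes factors. With prior effect
variance $W$ (prior sd 0.2 on the log-odds scale, the conventional
case-control default) and shrinkage $r = W/(W + se^2)$:

$$\log ABF = \tfrac12 \log(1 - r) + \tfrac12 z^2 r.$$

PIPs normalize the Bayes factors by log-sum-exp, which is exact in
double precision for log-ABFs beyond 700. The null-model row some
implementations add is omitted: every fine-mapped signal has already
passed genome-wide significance, so allocating posterior mass to "no
effect" would be inconsistent with the conditioning. The 95% credible
set is the minimal descending-PIP prefix reaching mass 0.95 (PIP ties
break by ascending position); its PIP-weighted average position,
rounded to base pairs, is the signal center used for gene distances,
and the locus is the credible-set span padded by 300 kb (clamped at
position 1). The center, not the nearest member, defines distance
because the selection rule is stated in terms of the weighted average
position.

## Gene-level association

Variants map to every gene body containing them (1-based inclusive
spans, no flanking window; a window is exposed for sensitivity
analyses), and genes with fewer than three mapped variants are dropped.
The gene statistic is the SNP-wise mean $T = K^{-1}\sum_k z_k^2$. Under
the null $z \sim N(0, R)$, so $KT = \sum_j \lambda_j \chi^2_1$ with
$\lambda_j$ the eigenvalues of the gene's variant LD matrix (taken from
the ancestry-matched panel and PSD-stabilized). The default tail
approximation moment-matches a scaled chi-square (mean $\sum\lambda$,
variance $2\sum\lambda^2$); an exact characteristic-function inversion
(Imhof) and a Monte-Carlo method are selectable. When all eigenvalues
are equal the distribution is exactly a scaled chi-square and is
evaluated exactly. Gene p-values map to one-sided probit z-scores
$z = \Phi^{-1}(1-p)$ (p floored at 1e-300), and ancestry-specific gene
z-scores meta-analyze by the $\sqrt{N}$ Stouffer rule using each
study's total effective sample size (per-gene sample sizes are not
tracked; this is flagged as an approximation).

Calibration, as asserted by the test suite on 2,200 null gene tests
with panel LD: the default approximation holds the type-I rate at
alpha = 0.05 inside [0.040, 0.060], but its bulk CDF deviation becomes
detectable by a Kolmogorov-Smirnov test at that sample size; the Imhof
method additionally passes the KS uniformity check at the 0.001 level.
The default favors speed and tail accuracy where gene hunting happens;
switch to `method = "imhof"` when well-calibrated mid-range p-values
matter.

## Feature-based gene scoring

Features are standardized genome-wide (zero-variance columns dropped
and logged). Marginal selection keeps features whose univariate
regression on the gene z vector has p < 0.05. Ridge regression with a
fixed penalty (default 100 added to the Gram diagonal; generalized
cross-validation per training fold is selectable) is fitted leaving out
one chromosome at a time; a gene's score is its held-out prediction, so
its own association never informs its score. Per-ancestry scores
combine by the $\sqrt{N}$-weighted mean and percentiles
$(rank - 1)/(G - 1)$ (average ranks for ties) are computed after the
combination, because the final report carries a single genome-wide
percentile per gene. The gene-gene correlation whitening step of the
original genome-wide scoring method is omitted; the interface accepts
an optional decorrelation transform applied to each training fold.

A caveat at small genome sizes: marginal selection is performed
genome-wide (as in the original method), so with few genes the
selection step itself can leak a strong held-out association into the
scores even though the ridge fit cannot. With the 80-gene synthetic
fixture this measurably inflates causal genes' scores; with thousands
of genes the effect is negligible. The leave-one-chromosome-out
guarantee proper — invariance of held-out scores to any perturbation of
the held-out chromosome's z-values at fixed selected features — is
exact and tested.

## Selection rule

Per locus, candidates are the genes whose bodies overlap the locus
interval (closed intervals; abutting genes count). Rule A selects the
gene with the top combined feature score if and only if it is also the
nearest gene to the credible-set center (distance 0 inside the body,
else distance to the nearest edge — edge distance, not TSS, because the
reference examples are stated gene-to-credible-set; a TSS mode is
configurable). Ties in either the argmax or the argmin void rule A
rather than picking arbitrarily. Rule B selects any gene whose
credible-set non-synonymous variants carry summed PIP strictly above
50% (the per-gene sum is used; a per-variant mode is available — with
sums, at most one gene can exceed 50%, so the at-most-one-gene
invariant is structural). When both rules fire, rule B wins. A gene
harbouring above-threshold non-synonymous PIP but lying outside the
locus interval is added as a candidate with a warning. At most one gene
is ever nominated per locus.

# The synthetic-data generator

Haplotypes follow a Gaussian copula: a latent normal vector with
block-AR(1) correlation $\rho$ is thresholded at the $(1-MAF)$ quantile
and a genotype is the sum of two independent haplotypes. This gives
analytic control of the LD structure for oracle tests but is not a
population-genetic model: there is no recombination map, no allele
ages, no frequency spectrum. Note that thresholding attenuates
correlation, so dosage LD is below the latent $\rho$; the test suite
checks convergence to the analytic copula-implied dosage correlation.

Summary statistics follow the standard summary-statistic likelihood
$z \sim N(\sqrt{N} R b,\, R)$ with per-allele scaling
$se = (2f(1-f)N)^{-1/2}$. Default study conditions: two ancestries with
effective sample sizes 127,626 (EUR) and 15,886 (EAS) — the sizes of a
large published two-ancestry Parkinson's disease meta-analysis — with
panel sizes 400/200, latent $\rho$ 0.9/0.8, 20 blocks of 88 variants at
5 kb spacing spread over 10 chromosomes, four 100 kb genes per block,
MAF uniform on (0.05, 0.5), and one causal variant per block with
per-SD effect $b = 10/\sqrt{N_{EUR}+N_{EAS}}$ (expected meta z of 10, a
clearly genome-wide-significant but not extreme signal). Five binary
pathway features contain every causal-pathway gene plus five random
others; 500 noise features are standard normal. The last four blocks
are "hard": their pathway membership points at the neighbouring gene
while the causal variant is flagged non-synonymous, so only rule B
recovers the truth there. These defaults are the generator's study
conditions; tests and the acceptance checks run against them unchanged.

What passing on this fixture does *not* show: robustness to real human
LD (long-range, admixture), to mis-specified panels, to binary-trait
liability-scale effects, to allele-frequency-dependent architectures,
or to feature matrices with the collinearity structure of real
expression/pathway data.

# Numerical choices

- LD matrices are symmetrized, and stabilized to PSD by adding
  $\varepsilon I$ with $\varepsilon = \max(0, 10^{-8} - \lambda_{min})$
  and rescaling by $1/(1+\varepsilon)$ so the diagonal stays exactly 1;
  Cholesky factorizations downstream can then never fail.
- The conditional-variance floor is 1e-6; candidates above $r^2 = 0.9$
  with the selected set are excluded as collinear.
- p-values from z are floored at 1e-300; probit z-scores are therefore
  always finite.
- The Imhof integral is evaluated with `integrate()` at rel.tol 1e-10;
  its practical accuracy is about 3e-5 on the slowest-decaying (K = 1)
  integrands, far below every tolerance used here. If the integrator
  fails it falls back to the moment-matched form.
- All randomness flows from a single master seed through fixed derived
  streams; identical seeds give byte-identical pipeline outputs.

# Problem sizes used by the validation suite

Chosen to make every check statistically meaningful at desk scale:
credible-set coverage uses 1,000 replicate 100-variant loci; gene-test
calibration uses 2,200 null gene tests; the conditioning oracle uses 50
regression instances; the clumping oracle 100 instances of 200
variants; the weighted-chi-square oracle 20 eigenvalue sets against
million-draw Monte Carlo; the end-to-end check the default 20-block
fixture, requiring at least 14 of 20 loci correct.

# Known limitations

- Bi-allelic autosomal SNVs only; no indels, no chromosome X (features
  for X are typically unavailable, and the thresholds assume SNVs).
- Single-causal-variant fine-mapping; overlapping signals are handled
  by conditioning, not by multi-causal search.
- Frequency-scale joint effect sizes are not reproduced; all joint
  inference is per-SD.
- The feature-scoring step omits gene-gene correlation whitening.
- Per-gene effective sample sizes are approximated by study totals in
  the $\sqrt{N}$ weights.
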