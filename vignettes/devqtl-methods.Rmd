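---
title: "Models and methods in devqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in devqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devqtl)
```

`devqtl` analyses how common genetic variants influence gene expression
across brain development, and classifies each regulatory effect by when in
development it acts. This vignette explains the statistical models, the
parameters that matter, the synthetic-data generator used to validate the
pipeline, and the numerical and design choices that were genuinely open.

## Cohort structure: periods, epochs, stages

Development is discretized into 12 periods (embryonic through adolescence),
grouped into four epochs: epoch 0 (periods 1–2), epoch 1 (periods 3–5),
epoch 2 (periods 6–8, the late-fetal transition), epoch 3 (periods 9–12).
Periods 1–6 are prenatal, period 7 transitional, periods 8–12 postnatal.
The default cohort layout is 176 samples: 112 prenatal, 4 transitional, 60
postnatal — the three sample cuts used by every association scan (complete,
prenatal-only, postnatal-only). Period boundaries are supplied by
configuration (`default_age_ranges()` gives post-conception-day intervals,
with birth at ~280 days); the generator assigns periods directly, so no
canonical age-to-period lookup is required.

## Expression preparation

**log2CPM.** Counts are converted as
$\log_2\!\big((c + 0.5)/(L + 1)\cdot 10^6\big)$ with $L$ the per-sample
library size. The pseudocount convention $(c+0.5)/(L+1)$ is the standard
variance-stabilized form; pseudocount-free CPM is kept separately because
the expressed-gene filter is defined on plain CPM.

**Expressed-gene filter.** A gene is retained if CPM ≥ 1 in at least 50% of
the samples of at least one period × sex stratum. The "at least 50%"
comparison is an exact fraction: 3 of 6 passes, 1 of 3 fails. The filter is
monotone — adding a sample whose CPM passes can never remove a gene.

**Hidden-factor adjustment.** Technical structure is removed with a
residual-PCA surrogate: each gene is regressed on period (categorical) and
sex, the top `n_hidden` principal components of the residual matrix are
computed by SVD, and their reconstruction is subtracted from the log2CPM
matrix. Period and sex signal is deliberately retained, because both
re-enter the eQTL model as covariates. A dedicated hidden-covariate or
surrogate-variable estimator could be substituted; the residual-PCA form
was chosen because downstream stages only require that structure orthogonal
to the known design be removed, and a linear projection is transparent and
directly testable (planting a known batch factor and verifying its removal).
One caveat is intrinsic to any residual-PCA definition: removing the top
$k$ components exposes components $k{+}1..2k$ on re-application, so strict
idempotence holds only when the hidden structure has rank ≤ `n_hidden`;
the test suite verifies idempotence in exactly that regime.

**Sex inference.** Expression of XIST (high in females) and a configurable
panel of chromosome-Y genes (high in males) is split per marker at the
midpoint of the two means from one-dimensional 2-means clustering; samples
are called by majority vote and flagged when the minority share reaches 25%
or only a single marker is informative.

**Epoch deltas.** Per gene, the median log2CPM in epoch 3 minus the median
in epoch 1 summarizes the late-fetal transition; genes whose other-epoch
median is ≤ −5 log2CPM are flagged epoch-specific (presence/absence rather
than amplification).

## Trajectory mixture model

Temporal dynamics are modeled as a finite mixture of $K$ polynomial
trajectories with Gaussian noise. Expression is IQR-normalized per gene
($({x - \mathrm{median}})/\mathrm{IQR}$; zero-IQR genes are passed through
and flagged), and each gene $g$ is one observation sequence across samples:

$$P(x_g) = \sum_{k=1}^{K} \pi_k \prod_s
  \mathcal{N}\!\big(x_{gs};\, p_k(u_s),\, \sigma_k^2\big),$$

where $p_k$ is a degree-4 polynomial on transformed age $u$ (log2
post-conception days, internally standardized for conditioning) and
$\sigma_k^2$ is component-specific but homoscedastic across samples. The
log transform keeps the prenatal range (weeks) and postnatal range (years)
comparable; a linear-age fit would compress all prenatal variation into a
sliver of the axis. Epoch-0 samples are excluded from fitting by an explicit
flag (`exclude_epoch0`), since very few samples there bias the curve near
the origin.

EM alternates responsibilities (E-step, log-sum-exp throughout) with
weighted polynomial least squares and variance updates (M-step). Components
whose mixing proportion falls below `min_prior` (default 0.05) are pruned
and EM continues with $K{-}1$ — requesting many components on three-group
data collapses back toward the truth. Defaults: `n_starts = 10` random
restarts, relative log-likelihood tolerance `1e-6`, variance floor 1e-10.
Model choice uses $\mathrm{AIC} = 2p - 2\ell$ and
$\mathrm{BIC} = p\ln G - 2\ell$ with $p = K(d{+}2) + (K{-}1)$ free
parameters ($d{+}1$ coefficients and one variance per component, $K{-}1$
free mixing proportions) and $G$ genes; BIC decides, ties to the smaller
$K$.

Components are labeled by the contrast of mean fitted values over epoch-3
ages versus epoch-1 ages: rising if the contrast exceeds `threshold`
(default 0.5 normalized units), falling below the negative threshold,
otherwise non-transitional. A numeric rule is required for automation;
the threshold is expressed in IQR-normalized units so it transfers across
genes. Genes are hard-assigned by maximum responsibility, with exact ties
broken toward non-transitional, then falling, then rising, so tie-breaking
is deterministic and conservative.

## Cell-type specificity

The tau index for a gene with non-negative expression over $n$ clusters is
$\tau = \sum_i (1 - x_i/\max_i x_i)/(n-1)$: 0 for uniform expression, 1 for
one-hot. Log-scale input is floored at 0 first (tau assumes non-negative
values). Markers for a cluster are the genes ranked 1 in that cluster
(dense descending ranks, ties sharing the smaller rank) with τ ≥ `min_tau`
(default 0.8), taking the top 10 by expression — a reproducible stand-in
for by-eye specificity screening. Marker-set temporal profiles use degree-1
LOESS (tricube-weighted local linear regression) with a ±1.96·SE pointwise
band.

## Cis-eQTL scans and genomic control

Variants enter the scan if their minor allele frequency is ≥ 5% in *both*
the prenatal and postnatal subsets and an exact Hardy-Weinberg test over
all samples gives p ≥ 1e-12. The HWE test enumerates the conditional
heterozygote distribution exactly, with a mid-p correction (the test is a
quality filter; mid-p avoids the conservatism of the plain exact test on a
discrete statistic).

Cis pairs are variants within 1 Mb of a gene's boundaries (0-based
half-open; the window anchors on gene boundaries, not the TSS). Each pair
is fitted by OLS of adjusted expression on alternate-allele dosage with
period (categorical), sex, and five ancestry PCs as covariates,
implemented by residualizing both sides on the covariate design
(Frisch–Waugh–Lovell), which matches the full design exactly and
vectorizes over hundreds of thousands of pairs. Dosage is coded 0/1/2
alternate alleles; flipping the coding negates the effect and leaves the
p-value unchanged. Benjamini–Hochberg FDR is computed separately within
each of the three cuts, over the pairs actually testable in that cut
(constant-dosage pairs are reported as missing and excluded from the FDR
family).

Calibration is validated by genomic control: 100 random draws of 500
same-chromosome gene–variant pairs 10–100 Mb apart (anchored TSS-to-variant,
consistent with the signed TSS-distance convention), scanned like cis
pairs; $\lambda$ is the median $\chi^2_1$ quantile of the p-values divided
by the $\chi^2_1$ median (~0.4549). Distant pairs should carry no cis
signal, so a well-adjusted scan gives $\lambda \approx 1$; the acceptance
script reports the median over the 100 draws on a 176-sample, 2,000-gene,
20,000-variant null cohort.

## Temporal classification

Per gene, the top pair is the one with the smallest FDR-significant
p-value from any cut (ties: smaller |TSS distance|, then variant id). The
prenatal and postnatal effects are contrasted with
$Z = (\beta_{pre} - \beta_{post})\big/\sqrt{SE_{pre}^2 + SE_{post}^2}$,
two-sided normal p, BH-adjusted over the top pairs only (the minimal
coherent family; the adjustment family was not fully specified by
convention, and top-pairs-per-gene is the smallest set on which the rule
operates). Categories, evaluated in order:

* **constant** — complete-cut FDR ≤ 0.05, same direction of effect
  (point-estimate signs) and unadjusted p ≤ 0.05 in both subset cuts;
* **prenatal-predominant** — prenatal FDR ≤ 0.05, postnatal p > 0.05,
  Z-test FDR ≤ 0.05; **postnatal-predominant** is the mirror image;
* otherwise **prenatal-trending** if $\beta_{pre} > \beta_{post}$, else
  **postnatal-trending** (exact ties go to postnatal-trending — an
  arbitrary but documented choice).

The first three categories are logically disjoint (constant requires both
subset p ≤ 0.05; the predominant classes require the other subset's
p > 0.05), so rule order cannot change a primary assignment. All
FDR-significant pairs of a gene inherit the top pair's category.
Alternative schemes (majority vote with the fixed tie order, second-best
variant, individual classification) and their concordance tables are
provided for sensitivity analysis.

Differential variance between stages uses an F test on residual variances
after residualizing, within each stage separately, on period, sex and five
ancestry PCs; the two-sided p doubles the smaller tail (sidedness was an
open choice; doubling the smaller tail is symmetric in the stage labels,
which the test suite verifies by swapping them).

## GWAS integration

**Matching and pruning.** GWAS SNPs are mapped to the eQTL-tested universe
directly or via the best proxy with r² > 0.8; unmatched SNPs are dropped
with a count. LD pruning is supervised by GWAS p-value: SNPs are processed
in ascending p (ties by position, then id) and kept unless in r² > 0.7
with an already-kept SNP within 500 kb — retaining the most associated SNP
of each clump deterministically, independent of input order.

**Matched permutation enrichment.** The tested universe (minus configured
exclusion regions, e.g. an HLA-like interval; empty by default in
simulation) is binned by MAF decile × gene-density decile, gene density
being the number of genes whose 1 Mb cis window contains the variant. Each
permutation replaces every GWAS SNP with a uniform draw from its bin,
excluding the SNP itself, independently across SNPs (with replacement) —
the null preserves the set's MAF and gene-density profile while breaking
its identity. Fold = observed eQTL proportion / mean null proportion;
empirical p uses the add-one rule $(r+1)/(n_{perm}+1)$ with "as or more
extreme" meaning null fold ≥ observed (one-sided enrichment).

**Colocalization.** Single-causal-variant Bayesian colocalization over
five hypotheses (H0 none, H1 GWAS only, H2 eQTL only, H3 both/distinct,
H4 both/shared). Per SNP and trait,
$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \frac{z^2}{2}\frac{W}{V+W}$
with $V = SE^2$ and prior effect variance $W = 0.15^2$ (the quantitative-
trait convention; priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$).
Hypothesis sums use log-sum-exp; the H3 cross-term is the product of the
marginal sums minus the diagonal, computed in log space. PP4 ≥ 0.8 is the
conventional evidence threshold for a shared causal variant.

**Gene-set tests.** Fisher's exact test of a query set against a
trait-associated set within the expressed-gene universe, with Bonferroni
correction for the stated family size (or BH across the family).

## The synthetic-data generator

The generator exists so every stage can be validated against known truth.
It emulates:

* the 176-sample developmental layout with per-period counts and
  non-overlapping age intervals; sexes Bernoulli(0.5), five ancestry PCs
  i.i.d. standard normal;
* biallelic variants in Hardy–Weinberg equilibrium with allele frequencies
  uniform in [0.05, 0.5] (20,000 variants across four 200 Mb chromosomes by
  default — long enough to sample 10–100 Mb distant pairs); optional LD
  blocks via a Gaussian copula with equicorrelated latent variables, the
  latent correlation solved numerically so pairwise genotype r² approximates
  the target at the mean MAF (real LD decay is out of scope);
* gene-level log2 expression as group polynomial trajectory + per-gene
  offset (SD 2) + planted eQTL dosage effects (stage-specific betas;
  transitional samples get the mean) + optional sex effect (default 0 — no
  autosomal sex-effect magnitude is established, so the default is null
  with a configuration hook) + Gaussian noise (SD 0.5);
* GWAS summary statistics with null Z ~ N(0,1) and causal
  |Z| ~ N(effect·√n, 1).

Default trajectory groups are rising / falling / flat with mixing
0.29 / 0.22 / 0.49 and slopes chosen so epoch-3 minus epoch-1 deltas are
roughly +2 / −1 / 0 log2 units — the magnitudes typical of late-fetal
transitions in bulk cortex.

Counts are produced by inverting the log2CPM transform against a target
library size (default 3e7 reads) rather than via a negative-binomial
model: downstream stages operate entirely on log2CPM, so
Gaussian-on-the-log-scale is exactly the structure they assume. Because
CPM is compositional, target CPM values are renormalized per sample to sum
to one million before inversion; a flat matrix is exactly round-trippable
when its level is the self-consistent $\log_2(10^6/G)$. A side effect
worth knowing: per-sample closure couples genes, so when many genes rise,
flat genes acquire a genuine (small) falling trend in CPM space — as they
do in real libraries.

What the generator does *not* emulate: recombination-map LD decay,
demography and ancestry stratification, multi-allelic variants or indels,
GC/length biases, count overdispersion beyond the log-normal, and
cell-composition changes underlying the trajectories. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated generative assumptions, not robustness to every artifact of real
RNA-seq.

## Problem sizes and determinism

The validation suite runs at desk scale: the genomic-control check uses a
176-sample × 2,000-gene × 20,000-variant null cohort (100 draws of 500
distant pairs); trajectory recovery uses 300 genes × 100 samples over 20
seeds; enrichment calibration uses 200 seeded runs at 2,000 permutations;
the scan's type-I error uses 10,000 null pairs. Every stochastic function
takes an explicit seed and regenerates byte-identical output for the same
seed.

## Known limitations

* The hidden-factor surrogate is a linear projection; nonlinear batch
  structure is out of reach, and results on real data adjusted with
  dedicated hidden-covariate or surrogate-variable methods will differ in
  detail.
* Association scans are plain OLS — no kinship/mixed models, no
  interaction (genotype × age) terms, no conditional secondary signals;
  trans-eQTLs are out of scope.
* Colocalization assumes a single causal variant per trait per locus.
* The exact-test HWE p-values are discrete; uniformity under the null
  holds in bulk but not at the extremes of the unit interval.
* Deciles degrade to coarser bins (with a warning) when the tested
  universe is small; matched permutation needs at least two candidates per
  occupied bin.
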