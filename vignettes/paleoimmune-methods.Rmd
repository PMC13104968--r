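---
title: "Methods: from dated genomes to directional pathway activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dated genomes to directional pathway activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoimmune)
```

paleoimmune is an inference stack for asking what natural selection did to
human biology over a time transect of ancient genomes: which traits it
pushed, which variants and genes carried the signal, and which biological
processes it turned up or down. Every stage consumes and produces standard
summary-statistic tables, so the stages compose but can also be used
alone. This vignette is the package's own account of the statistics: the
models, their assumptions, the defaults and why, and what the synthetic
data can and cannot certify.

## The selection statistic

The atomic signal is a per-variant time trend. For a cohort of dated
individuals with genotype dosages $d_{ij} \in \{0, 1, 2\}$, `run_scan()`
fits, per variant $j$,

$$ d_{ij} = \alpha_j + \beta_j t_i + \gamma_j^\top c_i + e_{ij}, $$

by weighted least squares, where $t_i = -\mathrm{date}_i/1000$ (analysis
time in kiloyears, so positive $\beta$ means the alternate allele rises
toward the present) and $c_i$ are ancestry covariates. The output is a
GWAS-shaped track (BETA, SE, Z, P, N, MAF per variant) that downstream
methods treat exactly like association statistics.

Choices that matter:

* **Covariates.** Admixture turnover confounds naive frequency-on-date
  regression: if ancestral components differ in allele frequency and
  their proportions shift over time, every variant trends. Including the
  ancestry proportions (or leading genotype PCs) as fixed effects removes
  this; the synthetic three-component schedule reproduces the failure
  mode and the fix. A mixed-model backend with a genetic relationship
  matrix could be swapped in behind the same interface; the fixed-effect
  version is what the package certifies.
* **Pseudo-haploid calls.** Individuals genotyped from a single read per
  site can only be 0 or 2. Such a dosage has twice the binomial variance
  of a diploid call, so those individuals enter with weight 0.5
  (`pseudohaploid_weight`).
* **Missingness** is complete-case per variant, recorded in `N`.
* **Filters.** `maf_min = 0.01` (monomorphic and near-monomorphic sites
  carry no trend information and destabilize the regression);
  `min_n = 30` non-missing genotypes.
* **Genomic control** (off by default) rescales all SEs by
  $\sqrt{\lambda}$ with $\lambda = \mathrm{median}(Z^2)/0.4549$. The
  normal-theory p-values are calibrated when residual dosage noise is
  sampling noise around a smooth frequency path; genetic drift at small
  effective population size adds autocorrelated path noise that the
  fixed-effect regression does not model, and genomic control is the
  blunt correction offered for that regime. The package's calibration
  claims (type-I error in [0.04, 0.06] at $10^4$ variants,
  Kolmogorov–Smirnov distance of Z to N(0,1) below 0.02) are made under
  infinite-population frequency paths with admixture structure and
  binomial genotype sampling — i.e. they certify robustness to
  *structure*, not to *drift*; drift behaviour is tested separately
  through the martingale and heterozygosity-decay properties of the
  simulator.

## Polygenic trajectory test

`compute_pgs()` scores each individual as the weighted dosage sum over
non-missing matched variants divided by the individual's non-missing
count; the per-individual normalization stops date-correlated missingness
from impersonating a trend. `gamma_test()` regresses scores on $t$ with
ancestry covariates; the slope (PGS units per kiloyear toward the
present) is the trajectory statistic.

Its null distribution is built by sign-flipping the per-variant weights
(fair flips drawn within minor-allele-frequency quintiles) and
recomputing the slope. Flips destroy the coupling between weight signs
and frequency trends while preserving the cohort's drift and structure
covariance, so the test is calibrated without modelling drift explicitly;
this is deliberately assumption-light rather than a drift-aware
parametric null. Because the slope is linear in the weights, each flipped
slope is a single inner product, and `B = 999` costs essentially nothing.
The empirical p-value uses the add-one rule, so its floor is $1/(B+1)$.

## Genetic correlation and meta-analysis

`estimate_h2()` regresses $Z_j^2$ on $N \ell_j / M$ with a free intercept
($\ell_j$ = LD score, $M$ = variant count). The slope is a
heritability-scale parameter; the intercept absorbs confounding
inflation. Weights follow the usual two-step scheme — an unweighted pass
supplies slope and intercept, then each variant gets weight
$1/(2v_j^2)$ with $v_j$ its model-implied variance. The variance floors
are *relative* (5% of the median model variance), which keeps the whole
estimator exactly invariant under the rescaling
$Z \to cZ,\ N \to c^2 N$.

`estimate_rg()` adds the cross-regression of $Z_{a}Z_{b}$ on
$\sqrt{N_a N_b}\,\ell_j/M$, whose slope is the genetic covariance
$\rho_g$; then $r_g = \rho_g / \sqrt{h^2_a h^2_b}$. A free cross
intercept absorbs sample overlap. When either heritability estimate is
non-positive, $r_g$ is reported missing rather than clipped — a
fabricated correlation is worse than an absent one. The selection track
has no conventional sample size; the scan's median `N` is used for
weighting, which leaves $\rho_g$ on an arbitrary but internally
consistent scale and $r_g$ (the sign/relative-magnitude readout)
invariant to that choice.

All standard errors are delete-one-block jackknives over 200 contiguous
variant blocks, and the leave-one-out series is retained so that
`meta_gls()` can pool correlated estimates across traits sharing the
block layout: pseudovalues give an estimate covariance $\Sigma$, the
pooled mean is the GLS average
$(\mathbf{1}^\top\Sigma^{-1}r)/(\mathbf{1}^\top\Sigma^{-1}\mathbf{1})$,
and $\Sigma$ is ridge-regularized by $\varepsilon\,\mathrm{tr}(\Sigma)/k$
(default $\varepsilon = 10^{-3}$) only when its condition number exceeds
$10^6$. With a diagonal $\Sigma$ this is exactly inverse-variance
weighting. The one-tailed default (`alternative = "less"`) reflects the
directional question the pooled analysis usually asks (did selection
*reduce* risk across a trait family); it is an argument, not a
commitment.

`partition_signal()` is the stratified variant: two annotation-specific
LD-score columns, slopes as per-variant signal densities, and the
annotation's share of total signal with a jackknife SE. Under the
synthetic exchangeable-block LD the annotation and complement scores are
close to collinear within a block, so the split is weakly identified at
desk scale — estimates are unbiased but carry honest, wide jackknife SEs.

## Colocalization and fine-mapping

`wakefield_abf()` computes the approximate Bayes factor
$\log \mathrm{ABF} = \tfrac12\log(1-r) + r z^2/2$, $r = w/(v+w)$, with
$v = 1/n$ on the standardized scale and prior effect variance
$w = 0.04$ — the conventional default, applied to the selection track as
well for want of an established prior scale there (configurable per
track). `coloc_abf()` enumerates the five single-causal hypotheses with
priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; all sums run in log
space. The H3 term (different causal variants) is *not* computed as
$\Sigma_a \Sigma_b - \Sigma_{ab}$, which cancels catastrophically when
one variant dominates both tracks, but as a sum of per-variant
complements — this is what lets a 1,000-locus fuzz suite match a direct
natural-scale enumeration oracle to $10^{-8}$ relative error.

`finemap_single()` normalizes ABFs under a uniform single-causal prior
into posterior inclusion probabilities; the 95% credible set is the
minimal descending-PIP prefix (ties broken by genomic position, for
determinism) reaching 0.95. Only the single-causal model is offered;
loci suspected of harbouring independent signals should be split by
`define_loci()` rather than residualized. `joint_pip()` multiplies the
per-variant shared-causal posterior (conditional on colocalization) by
PP(H4) to give the unconditional shared-variant posterior. A PP(H4)
threshold of 0.8 is the package's default reading of "colocalized" where
a gate is needed; it is exposed, not hard-wired.

## Pathway enrichment and the immune-label test

`hypergeom_enrich()` tests each pathway's overlap with a prioritized
gene set by the upper-tail hypergeometric distribution, always against a
caller-supplied universe — the set of genes that *could* have been
prioritized, never the whole genome — with pathways intersected with the
universe before testing. Odds ratios use Haldane's 0.5 correction only
when a cell is zero. `bh_fdr()` is a validated wrapper over the standard
Benjamini–Hochberg step-up.

`immune_label_test()` asks whether enriched pathways (q < 0.10) are
disproportionately immune-labelled, via logistic regression on the
immune flag plus log pathway size. Its permutation null re-draws the
*prioritized gene set* (uniformly from the universe, same size) and
reruns everything; resampling genes rather than shuffling labels keeps
the redundancy of gene content across pathways — the thing that makes
naive label tests anti-conservative — intact under the null. Complete
separation in the logistic fit falls back to the 2×2 Haldane odds ratio
with a flag, never silently.

## Signed pathway activity

For pathways whose members are all positive or all negative regulators
of a process, direction of selection on the process is inferable from
protein QTLs. `gene_covariance()` averages, over variants with |Z| > 3
for *both* selection and the protein's level, the product of
standardized effects $(Z_{\mathrm{sel}}/\sqrt{N_{\mathrm{sel}}})\cdot
(Z_{\mathrm{pQTL}}/\sqrt{N_{\mathrm{pQTL}}})$. The product-based
estimator (rather than a per-gene bivariate LD-score regression) is
deliberate: per-gene heritabilities are too noisy to normalize by, and
the |Z| filter concentrates the average on variants that carry signal in
both tracks. The genome-wide `estimate_rg()` remains available as a
qualitative cross-check of the sign.

`pathway_activity()` averages $\mathrm{sign}_g \times \mathrm{cov}_g$
over regulator genes, so a positive statistic always reads "activity
increased". Inference uses a delete-one-block jackknife over the
genome-ordered union of qualifying variants across the pathway's genes
(shared blocks, so co-regulation covariance between genes is respected).
A gene whose qualifying variants sit inside a single block would make a
leave-one-out replicate empty, so it is dropped; the drop is iterated to
a fixed point, making it idempotent. Two hygiene rules matter at
simulation scale: jackknife blocks must be *coarse relative to LD*
(each leave-out unit should span several LD blocks — the calibration
runs use a 10,000-variant genome with 50 blocks, i.e. ~8 LD blocks per
leave-out unit), and the default `n_blocks = 200` presumes a
genome-wide qualifying union, which real pQTL data provide.

`activation_summary()` tabulates inferred direction against immune
labels among FDR < 10% pathways, computes the immune-increased odds
ratio, and attaches a one-tailed label-shuffle permutation p-value. A
zero margin leaves the odds ratio undefined and flagged.

## The synthetic-data generator

The generator exists so every claim above is testable end to end. It
emulates the statistical *structure* of the real inputs, not their
content:

* **Frequency paths**: Wright–Fisher binomial resampling with additive
  selection, $p' = p + sp(1-p)$ then binomial sampling of $2N$ gametes,
  per ancestral component; a deterministic mode (infinite $N$) isolates
  selection from drift. Defaults: 400 generations at 25 years/generation
  (a 10,000-year transect), $N = 10{,}000$, 10% of variants selected
  with $|s| \in [0.005, 0.02]$ and random sign.
* **Cohorts**: dates uniform over the transect; ancestry Dirichlet-drawn
  around a piecewise-constant three-component admixture schedule
  (hunter-gatherer-like → farmer-dominated → steppe-admixed), which is
  what makes the structure confounding real; binomial diploid genotypes
  from the ancestry-mixed frequency; 5% missingness and 30%
  pseudo-haploid individuals by default, rates typical of ancient
  panels.
* **LD**: block-diagonal with exchangeable within-block correlation
  varying across blocks (even spread 0.15–0.85 by default). Equal
  blocks with a single $r$ make every LD score identical and the
  LD-score regression unidentifiable — the across-block spread is what
  gives the regressions their leverage, and it keeps every LD score
  analytic: $\ell_j = 1 + (m-1)r_b^2$.
* **Summary statistics**: standardized causal effects drawn jointly
  across tracks at a target correlation, then LD-propagated:
  $Z = \sqrt{N}\,R\beta + \eta$, $\eta \sim N(0, R)$, so
  $E[Z_j^2] = 1 + N\ell_j h^2/M$ and
  $E[Z_{a,j}Z_{b,j}] = \sqrt{N_aN_b}\,\ell_j\rho_g/M$ hold exactly —
  the identities the regressions estimate. pQTL tracks add a per-gene
  cis component and a genome-wide component scaled by a signed coupling
  to the selection effects; the no-noise mode (`noise = FALSE`,
  `h2_cis = 0`) makes coupling-sign flips negate downstream statistics
  exactly, which the antisymmetry tests exploit.
* **Pathways**: collections with immune labels and disjoint
  positive/negative regulator subsets, GMT-serializable and
  byte-reproducible under a fixed seed.

What passing tests do **not** show about real data: no recombination
maps or realistic LD decay, no ancient-DNA damage or contamination, no
date uncertainty, no realistic demography beyond the three-component
schedule, and drift-scale path autocorrelation is excluded from the
scan's calibration claim (see above). The generator's defaults are
chosen for testability at desk scale, not to match any published
cohort.

## Problem sizes and numerical conventions

The shipped test and acceptance runs use: $10^4$ variants × 400
individuals for scan calibration; 500 cohorts (150 × 300) for the
trajectory null; 50,000 variants (1,000 blocks × 50) for genetic
correlation, meta-analysis and partitioning; 500 loci of 50 variants for
credible-set coverage; 1,000 random loci (≤ 10 variants) for the
colocalization oracle; and 100 seeds × 8 pathways on a 10,000-variant
genome for the activity null. These sizes put Monte-Carlo error
comfortably inside the tolerances asserted while keeping a full run in
minutes on one core.

Numerical conventions, collected: analysis time is $-\mathrm{date}/1000$
(positive slope = rising toward the present); all probability sums run
in log space with explicit complement handling; credible-set ties break
by position; jackknife SEs use the delete-one-block formula
$\sqrt{\tfrac{B-1}{B}\sum_b(\hat\theta_{(-b)} - \bar\theta)^2}$;
empirical p-values use the add-one rule; degenerate cases (singleton
groups, zero-margin tables, separated regressions, all-dropped gene
sets) return flagged or missing values, or error with reasons — never a
silently fabricated number.
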