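---
title: "Case-control metagenome-wide association analysis with metamwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control metagenome-wide association analysis with metamwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`metamwas` implements the statistical core of a shotgun-metagenomics
case-control association study (MWAS). Starting from a per-genome
mapped-read-count table, an ORF/gene depth table and per-sample phenotype
and covariate data, it

1. builds relative-abundance tables at six taxonomic levels (L2 phylum ...
   L7 species) by genome-length normalization, ancestor aggregation and
   per-sample compositional closure;
2. filters features by detection fraction, group presence and mean
   abundance;
3. normalizes clade abundances by a per-feature maximum-likelihood Box-Cox
   transform and gene abundances by per-sample depth scaling followed by a
   rank-based inverse normal transform;
4. tests each feature with a covariate-adjusted logistic regression
   (case/control as the response, the transformed abundance as the
   exposure, two-sided Wald P);
5. calibrates significance empirically by phenotype permutation: the
   metagenome-wide threshold is the Harrell-Davis 95th percentile of the
   permutation null of the scan's minimum P, and rank-wise 90th-percentile
   null quantiles give empirical FDR calls at level 0.1;
6. runs effect-size-ranked gene-set enrichment, an MWAS-GWAS
   pathway-overlap test, and alpha/beta-diversity comparisons.

Because real case-control gut-metagenome cohorts are typically
access-restricted, the package ships a synthetic-cohort generator whose
defaults emulate the target study design (26 cases, 77 controls) so that
every stage runs, and is tested, end to end without any download.

# The abundance model behind the generator

Each species $s$ carries a latent baseline log-intensity
$\mu_s \sim N(0, \sigma_\mu^2)$ (default $\sigma_\mu = 2$, giving the
heavy-tailed rank-abundance curves typical of gut profiles). Sample $i$'s
latent intensity is

$$\log \lambda_{si} = \mu_s + \delta_s \, \mathrm{case}_i
  + b_s \frac{\mathrm{age}_i - 50}{10} + \varepsilon_{si}, \qquad
  \varepsilon_{si} \sim N(0, \sigma^2),$$

with $\sigma = 1$ by default. A Bernoulli presence indicator (default
dropout 0.2) multiplies $\lambda$ to create zero inflation, and
`spec$depth` reads per sample (default $5\times10^6$) are drawn
multinomially with probabilities proportional to intensity times genome
length — so the length normalization that `quantify_taxa()` applies is
actually undoing something. Ages are truncated normal on $[20, 90]$ and sex
is Bernoulli, with per-group parameters so that deliberate confounding can
be planted; the age slopes $b_s$ vary per feature because a slope common to
all features would be a per-sample factor that compositional closure
removes exactly.

Two generator choices deserve emphasis:

* **Spikes act on log-intensity before closure**, matching the additive
  effect the association model estimates after transformation.
* **Spiked features are placed in the low-abundance tail** of the baseline
  distribution. Under compositional closure it is mathematically impossible
  for some features to shift by $\delta$ while all others stay exchangeable
  between groups — the fractions must sum to one — unless the spiked mass
  share is negligible. Placing spikes in the tail keeps that share well
  below 1%, making the "non-spiked features are exchangeable" contract hold
  to high accuracy; it also mirrors the empirical observation that
  disease-associated taxa are rarely the dominant commensals.

What the generator does **not** emulate: phylogenetic correlation between
related species, strain-level variation, batch effects, sequencing error,
and realistic gene-to-pathway structure. Passing tests therefore demonstrate
the statistical machinery's correctness and calibration under the stated
model, not robustness to every failure mode of real data.

# Feature filters

A clade is removed when it is detected (strictly positive) in fewer than
20% of samples, in no case sample or no control sample, or with a mean
relative abundance below 0.001% ($10^{-5}$ as a fraction); an exclusion
list provides the hook for contaminant/batch flags from reference cohorts.
Gene filters use the first two rules only. "Detected" means strictly
positive — counts and depths are nonnegative and no detection floor is
specified, so zero is the only defensible threshold. The boundary is
strict: a feature present in exactly 20% of samples is retained.

# Normalization

`boxcox_transform()` maximizes the normal profile log-likelihood (with the
Jacobian term) over $\lambda \in [-3, 3]$, a coarse 0.25 grid followed by
golden-section refinement (`stats::optimize`); the $\lambda = 0$ branch is
the natural log. Zeros are handled by adding half of the smallest positive
value before transforming — a pseudocount convention; an explicit shift can
be supplied instead. The transform is fitted per clade: each feature gets
its own $\lambda$, matching the per-feature association models downstream.

`rank_int()` uses the Blom offset $c = 3/8$,
$y_i = \Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$, the conventional
default in genetic association work; ties receive average ranks.

# Association scans

The phenotype is the response (binomial family, logit link) and the
transformed feature abundance the exposure, plus covariates — sex and age
for gene scans; sex, age and the top three principal components (computed
from the Box-Cox-transformed species table, standardized to unit variance)
for clade scans. Effect sizes are log odds ratios, consistent with
case-control designs. A Gaussian variant (abundance as the response) is
available for sensitivity analysis. Constant features, single-class
phenotypes and (quasi-)separated fits are flagged with reason codes and
`NA` rather than silently reported.

The PC covariates are computed on the **correlation** basis (features
standardized before the eigendecomposition; `scale = FALSE` restores
covariance PCA). This is a deliberate choice: per-feature Box-Cox
transforms leave widely different variances, and covariance PCA of such a
table largely reproduces the few highest-variance features — including any
strongly differential one, which conditioning would then erase (in a
60-species simulation with one spiked clade, PC1 correlated 1.0 with the
spiked feature and the adjusted scan lost it entirely; on the correlation
basis it is recovered at the scan top). Correlation PCs capture shared
community structure, which is what a population-stratification-style
covariate is meant to be.

The permutation framework refits the same logistic model $B \times m$
times, so the package carries a compiled IRLS engine (hand-accumulated
normal equations, small-matrix Cholesky) that reproduces `stats::glm`
Wald statistics to $10^{-6}$; the test suite asserts that equivalence.
`stats::glm` remains the default reporting engine because its convergence
diagnostics are richer.

# Empirical thresholds

Case/control labels are permuted (the case:control ratio is preserved,
covariates travel with their samples), the full covariate-adjusted scan is
re-run per permutation, and each permuted scan's $-\log_{10} P$ values are
stored sorted. The metagenome-wide threshold $-\log_{10}(P_{sig})$ is the
Harrell-Davis 95th percentile of the null minimum-P column (production
default $B = 50{,}000$; calibration studies here use $B = 1{,}000$), with a
percentile-bootstrap 95% CI. Rank-wise 90th percentiles of the null columns
give per-rank FDR thresholds at level 0.1; a feature is called when its
rank's observed statistic exceeds the rank's threshold and all better ranks
are also called (step-down contiguity, preventing isolated deep-rank
calls — the description leaves non-monotone exceedance resolution open, and
contiguity is the conservative resolution).

Numerical conventions: permutation P-values use $(b+1)/(n_{perm}+1)$ and are
never exactly zero; the Harrell-Davis estimator is the beta-weighted sum of
order statistics, which the tests check against numeric integration of the
incomplete beta weights to $10^{-10}$.

## Operating characteristics (what the calibration studies compute)

`simulate_threshold_calibration()` generates independent *null* cohorts
(default 500 cohorts, 25 cases / 25 controls, 100 species, $B = 1{,}000$)
and measures how often the observed minimum-P statistic exceeds the
cohort's own threshold; by permutation exchangeability this converges to
the nominal 0.05, and the packaged run reproduces it.

`simulate_fdr_calibration()` plants 5 spiked features of log-effect 2 among
100 (100 cases / 100 controls) and measures the realized FDR of the
rank-wise calls. **Known limitation:** the rank-matched procedure compares
the observed rank-$r$ statistic with the null distribution of rank $r$
computed over *all* features. When $k$ true signals occupy the top ranks,
the observed rank-$(k{+}j)$ statistic is the $j$-th largest among the
remaining null features, so it is systematically compared against a
too-deep null rank; with contiguous step-down calling this inflates the
realized FDR well above the nominal level whenever the signal fraction is
non-negligible (at 5 signals in 100 features the inflation is severe — an
exchangeable pure-null reconstruction shows the same behaviour, so it is a
property of the procedure, not of the generator or the implementation).
In the sparse regime the procedure was designed for (a handful of signals
among hundreds of features), the misalignment is one of a few ranks and
the calls remain nearly nominal. The package implements the procedure as
specified and reports its measured operating characteristics rather than
substituting a different FDR estimator.

# Enrichment and pathway overlap

Genes are ranked by signed effect size (descending, ties broken by id).
The enrichment score is the signed extremum of the weighted
Kolmogorov-Smirnov running sum (hit increments proportional to $|\beta|$,
weight exponent 1; miss increments uniform), the classic preranked-GSEA
statistic. Sets intersected to fewer than 50 or more than 30,000 ranked
genes are excluded, as is any set covering the whole list (the miss
increment is undefined). Significance comes from membership permutation:
$P = \min(1,\, 2(b+1)/(n_{perm}+1))$ counting same-sign exceedances in
magnitude, Bonferroni-adjusted over tested sets. No multilevel/adaptive
P refinement is attempted.

The MWAS-GWAS interaction test classifies shared pathways at $P < 0.05$
in each list and applies the two-sided Fisher exact test
(probability-mass rule — the convention of `stats::fisher.test` — stated
explicitly because two-sided conventions differ).

# Diversity

Samples are rarefied without replacement to a common depth (production
default $3\times10^6$ reads; tests and the demo use $10^3$–$10^4$). The
Shannon index uses the natural log. The case-control comparison uses
Welch's t-test by default (with Student's variant selectable — the two are
both in circulation for this design and the package does not privilege
either beyond the unequal-variance default). Beta diversity uses
Bray-Curtis dissimilarity and a PERMANOVA pseudo-F,
$F = \frac{SS_{between}/(g-1)}{SS_{within}/(n-g)}$ with
$SS_{total} = \sum_{i<j} d_{ij}^2 / n$, tested by label permutation
(default $10^5$) or exhaustive enumeration for small $n$; `vegan::adonis2`
serves as an independent oracle in the tests.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` wires the stages in order and writes TSV results plus a
JSON provenance record (package version, seed, thresholds, derived
quantities). A single root seed deterministically derives per-stage seeds,
so any stage can be re-run in isolation and full runs are byte-identical
under a fixed configuration. The test suite exercises the pipeline on a
26/77-sample demo cohort with 40 species and 120 genes at reduced
permutation counts ($B = 200$), while the calibration studies use the
problem sizes stated above; production defaults
($B = 50{,}000$ permutations, $10^5$ PERMANOVA permutations,
rarefaction to $3\times10^6$) are set in `default_config()`.

# Degenerate inputs and tie-breaks

Constant features are rejected by the transforms ("degenerate feature")
and flagged by the scans; all-zero samples are an error with the sample
named; samples below the rarefaction depth are an error with the sample
named; GMT lines with fewer than three fields are rejected; duplicate set
members are deduplicated with a warning. Ranking ties in GSEA break by
feature id; PC signs are fixed by making each component's
largest-magnitude loading positive.
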