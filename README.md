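# metamwas

Case-control **metagenome-wide association analysis** (MWAS) for shotgun
gut-metagenome cohorts, with permutation-calibrated significance
thresholds.

Shotgun sequencing yields, per sample, mapped-read counts for thousands of
reference genomes and depths for hundreds of thousands of predicted genes.
Comparing cases with controls on such data raises four statistical problems
this package addresses for the analyst:

1. **Abundance construction** — genome-length-normalized counts aggregated
   into relative abundances at six taxonomic levels (L2 phylum ... L7
   species), with detection/abundance/contaminant filters and PCA-based
   outlier flagging.
2. **Normalization** — per-feature maximum-likelihood Box-Cox transforms
   for clade fractions; per-sample depth scaling plus rank-based inverse
   normal transformation for gene abundances.
3. **Covariate-adjusted association** — per-feature logistic regression
   (case/control ~ abundance + sex + age [+ top-3 community PCs]), giving a
   log-odds effect size and a two-sided Wald *P* per feature.
4. **Empirical significance** — because features are many, correlated and
   non-normal, multiplicity is calibrated by phenotype permutation: with
   *B* label permutations of the full scan, the metagenome-wide threshold
   is

   &nbsp;&nbsp;−log₁₀(*P*<sub>sig</sub>) = HD₀.₉₅( −log₁₀ *P*<sub>min</sub><sup>(1)</sup>, ..., −log₁₀ *P*<sub>min</sub><sup>(B)</sup> ),

   the Harrell–Davis 95th percentile of the null minimum-*P* distribution
   (bootstrap 95% CI), and rank-wise 90th percentiles of the sorted null
   scans give empirical FDR-0.1 calls, rank by rank with step-down
   contiguity.

Downstream, effect-size-ranked gene-set enrichment (weighted
Kolmogorov–Smirnov running-sum score, membership-permutation *P*),
a Fisher-exact MWAS–GWAS pathway-overlap test, and alpha/beta-diversity
comparisons (rarefaction, Shannon index with Welch/Student *t*,
Bray–Curtis + PERMANOVA) complete the pipeline.

Real cohorts of this design are typically access-restricted, so the
package includes a synthetic-cohort generator (compositional, zero-inflated,
log-normal abundances with optional spiked effects and covariate
structure, default 26 cases / 77 controls) that makes every stage runnable
and testable offline.

## Worked example

```r
library(metamwas)

cfg <- default_config(
  seed = 7L,
  simulate = list(n_case = 26, n_control = 77, n_species = 150,
                  n_genes = 300, zero_inflation = 0.2, depth = 1e6,
                  spike_species = data.frame(feature_id = "s0012", delta = 2),
                  spike_genes = NULL),
  thresholds = list(B = 2000, alpha = 0.05, fdr_level = 0.1, n_boot = 500),
  gsea = list(min_size = 25, max_size = 30000, n_perm = 1000),
  diversity = list(rarefy_depth = 1e5, permanova_perm = 9999,
                   alpha_variant = "welch"))
res <- run_pipeline(cfg, "demo_run")
```

This simulates a 26/77 cohort in which species `s0012` carries a planted
case-control log-abundance shift of 2, then runs the full pipeline
(B = 2000 permutations for the thresholds). The run prints stage timings
and leaves TSV results plus `provenance.json` in `demo_run/`. Headline
numbers from this exact configuration:

```
p_sig (-log10): 3.061   CI [ 3.018, 3.102 ]
FDR calls: 2 -> s0012, s0110
 feature_id       beta        se            p
      s0012  0.1553293 0.0379746 4.307286e-05
      s0110 -1.6138142 0.4951346 1.116700e-03
alpha-diversity Welch p: 0.99 ; PERMANOVA F: 0.626  p: 0.913
```

Reading: the metagenome-wide significance threshold for this cohort is
−log₁₀ *P* = 3.06, i.e. a single-feature *P* must fall below ~8.7×10⁻⁴ to
be scan-wide significant at α = 0.05. The spiked species is the top
association (*P* = 4.3×10⁻⁵, above the threshold) and is called at
empirical FDR < 0.1; one null feature (`s0110`) is co-called, illustrating
the procedure's tendency to over-call ranks just below true signals (see
the methods vignette). Alpha- and beta-diversity show no case-control
difference, as expected when only one low-abundance clade differs.

Individual stages are exported (`quantify_taxa()`, `filter_clades()`,
`boxcox_transform()`, `rank_int()`, `run_mwas()`, `permute_null()`,
`empirical_bonferroni()`, `empirical_fdr()`, `gsea_preranked()`,
`pathway_overlap()`, `permanova()`, ...), and a thin command-line wrapper
lives at `inst/cli/metamwas.R` (`run-all`, `simulate`).

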