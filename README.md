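# tcdissect

Dissects bulk tumor transcriptomes into **consensus independent
transcriptional components** (TCs) and carries them through a complete
prognostic analysis: gene-set annotation, survival association under
permutation-controlled false-discovery, proximity-based patient
stratification with a random survival forest, and projection onto
independent bulk, spatial and single-cell expression profiles. A
synthetic-data generator with known ground truth validates every stage
end to end.

The package is written for computational oncologists and statisticians
working with heterogeneous bulk expression cohorts (for example early
colorectal cancer) who want latent transcriptional programs, rather than
single genes, as the unit of prognostic analysis.

## The method

A gene-centered expression matrix $X$ ($p$ genes $\times$ $n$ samples) is
modelled as $X = S^\top A + E$ with statistically independent gene-weight
components in the rows of $S$ ($i \times p$, each standardized to mean 0,
SD 1) and per-sample activities $A$ ($i \times n$). The pipeline:

1. **Consensus ICA** (`cica`) — PCA on the between-sample covariance
   selects the smallest $i$ capturing ≥ 85% of variance; 25 randomly
   initialised fixed-point ICA runs (log-cosh contrast) are clustered
   across runs at $|r| > 0.9$ (cluster size capped at the run count);
   clusters are averaged into consensus TCs, each with a **credibility
   index** (cluster size / runs, retained at ≥ 0.5); the mixing matrix is
   re-estimated by least squares.
2. **Enrichment** (`enrichment_table`) — Welch t between in-set and
   out-of-set gene weights, transformed to a signed standard-normal
   Z-score, Bonferroni-corrected; gene sets filtered to 10–500 genes;
   `important_genes` reports $|weight| \ge 3$.
3. **Survival** (`fit_cox`, `permutation_fdr_select`) — univariate and
   covariate-adjusted Cox regression inside a multivariate permutation
   framework (10,000 permutations) controlling the false discovery
   proportion at 5% with 80% confidence.
4. **Random survival forest** (`surv_forest`) — 1000 log-rank-split trees,
   5 randomly chosen TCs per tree, no bootstrap; the element-wise sum of
   co-terminal-node indicators is the proximity matrix (diagonal =
   n_trees), clustered with Ward D2; per-TC importance is the
   candidacy-normalised usage fraction.
5. **Projection** (`project`, `match_components`,
   `permutation_activity_significance`, `single_cell_activity`) —
   cross-dataset activity estimation, split-dataset robustness matching at
   $|r| > 0.5$, and gene-label permutation significance maps for spatial
   spots (5000 permutations) and single cells (3000 permutations, Johnson
   normalisation, 10% subsampling).

`simulate_cohort` generates the synthetic ground truth (sparse
super-Gaussian sources, Gaussian activities and noise, proportional-hazards
survival with realistic clinical covariates, planted and null gene sets);
`run_full` and `run_sensitivity` orchestrate complete reproducible runs.

## Worked example

```r
library(tcdissect)

sim <- simulate_cohort(seed = 1)        # 1000 genes, 5 sources, 300 samples
fit <- cica(sim$expression, n_runs = 25, seed = 42)
fit
#> Consensus ICA decomposition
#>   300 samples, 1000 genes; 5 PCA dimensions (>= 85% variance)
#>   25 ICA runs -> 5 consensus TCs (credibility >= 0.50)
#>   reconstruction R^2 = 0.912

round(abs(cor(t(fit$components$weights), t(sim$truth$weights))), 2)
#>       S1   S2   S3   S4   S5
#> TC1 0.03 1.00 0.03 0.03 0.03
#> TC2 1.00 0.03 0.03 0.03 0.03
#> TC3 0.03 0.03 0.03 1.00 0.03
#> TC4 0.03 0.03 1.00 0.03 0.03
#> TC5 0.03 0.03 0.03 0.03 1.00

sel <- permutation_fdr_select(coef(fit), sim$survival,
                              n_perm = 1000, seed = 7)
sel
#> Permutation FDP selection (univariate, 1000 permutations, FDR 5% at 80% confidence)
#>   selected 2 components (p <= 4.06e-04): TC1, TC2
```

Each consensus TC matches exactly one planted source at $|r| \approx 1$
with credibility 1.0, and the reconstruction captures ~91% of the
gene-centered variance (the rest is the injected noise). The permutation
framework selects the hazard-driving component (TC2, which recovers the
planted driver S1 at p below 1e-20); in this replicate a second,
borderline component is also admitted at p = 4e-4 — the framework
controls the false-discovery *proportion* with 80% confidence over
replicates, not per-replicate certainty.

Downstream, `surv_forest(coef(fit), sim$survival)` stratifies the cohort
on the forest proximity matrix and `project(fit$components, X_new)`
transfers the components to independent data.

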