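---
title: "Dissecting bulk transcriptomes into consensus independent components"
author: "tcdissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting bulk transcriptomes into consensus independent components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdissect)
```

## The model

Bulk tumor expression profiles are mixtures: each sample's transcriptome
superimposes the transcriptional programs of malignant cells, stroma and
immune infiltrate, plus technical variation. `tcdissect` models a
genes-by-samples matrix $X$ ($p \times n$, log-scale, gene-centered) as

$$X = S^\top A + E,$$

where the rows of $S$ ($i \times p$) are statistically independent
*transcriptional components* (TCs) — gene-weight vectors standardized to
mean 0, SD 1 across genes, so a weight acts like a z-score — and $A$
($i \times n$) is the *mixing matrix* of per-sample activities. Independent
component analysis estimates $S$ by maximising non-Gaussianity; the sparse,
heavy-tailed structure of real transcriptional programs is exactly what ICA
exploits.

### Consensus ICA

A single ICA run depends on its random initialisation. `cica()` therefore:

1. selects the dimensionality $i$ as the minimum number of top principal
   components of the between-sample covariance matrix capturing at least
   85% of total variance (`variance_threshold`);
2. performs 25 (`n_runs`) fixed-point ICA runs (log-cosh negentropy
   contrast, symmetric decorrelation, tolerance $10^{-6}$, at most 1000
   iterations) on the whitened data, each from a fresh random
   unit-variance weight matrix;
3. clusters components across runs whose pairwise $|r| > 0.9$
   (`r_threshold`), greedily in descending-$|r|$ edge order; merges are
   refused if they would exceed the number of runs, include two components
   from one run, or break full mutual correlation within the cluster;
4. averages each cluster's sign-aligned members into a consensus TC and
   re-standardizes; the *credibility index* is cluster size divided by the
   number of runs, and TCs below 0.5 (`credibility_threshold`) are dropped;
5. re-estimates $A$ by ordinary least squares of the gene-centered data on
   the consensus weights (consensus averaging destroys the exact unmixing
   inverse of any single run, so the mixing matrix must be re-fit).

Sign conventions in ICA are arbitrary; each consensus TC is oriented so its
gene-weight skewness is positive (ties resolved by making the
largest-magnitude weight positive), which makes `cica()` deterministic
given its master seed. Components are ordered by descending credibility,
then by explained activity variance.

The PCA is performed on the covariance (not correlation) between samples;
genes are mean-centered across samples but not rescaled. This is the fixed
convention that the least-squares mixing estimation, reconstruction
$R^2$ bookkeeping and projection all share.

## Gene-set annotation

Each TC is annotated by a two-sample Welch $t$-test (unequal variances,
Welch–Satterthwaite degrees of freedom) comparing the weights of genes
inside a set against all remaining profiled genes. To compare sets of
different sizes the two-sided $p$ is transformed into a signed
standard-normal Z-score; the transform is computed in log space so extreme
$t$ statistics map to finite Z values rather than overflowing to infinity.
Sets are filtered to 10–500 genes *after* intersection with the profiled
universe; Bonferroni correction runs over the full components-by-sets
table (a single collection per call — per-collection correction when
multiple collections are scored separately). Genes with $|weight| \ge 3$
are reported as a TC's important genes; activities are related to
continuous covariates by Spearman rank correlation.

The null calibration of the Z-score (standard normal over random gene
sets) is exact when the weight profile is continuous and roughly normal;
for extremely sparse profiles with a near-constant background the Welch
denominator becomes erratic and the null is under-dispersed. The test
suite checks calibration on a normal-weight component and checks planted
signal detection on the sparse synthetic sources.

## Survival association

`fit_cox()` fits a proportional-hazards model of disease-free survival on
one TC's activity, z-scored so the hazard ratio is per SD (Efron tie
handling; Breslow optional). Categorical clinical covariates keep an
explicit `"unknown"` level instead of dropping rows — real early-CRC
cohorts have up to half of molecular annotations missing.

`permutation_fdr_select()` controls the *false discovery proportion* with
stated confidence: observed per-TC $p$-values are compared with the joint
null distribution obtained by permuting the (time, event) pairs against
the samples (covariates stay attached to their samples). The selection
threshold is the largest observed-$p$ cutoff $t$ such that, with
probability at least `confidence` (default 0.8) over the permutation
distribution, the number of null features at or below $t$ is at most
`fdr` (default 0.05) times the observed rejection count. Counting the
observed vector as one member of the permutation set makes the procedure
conservative: under a global null with $B$ permutations the probability of
any selection is exactly $\lceil (1-\text{confidence})(B+1) \rceil / (B+1)
\le 1 - \text{confidence}$, because the event requires the observed
minimum $p$ to rank in the lower $(1-\text{confidence})$ tail of its own
exchangeable permutation distribution. A Monte Carlo check of this bound
over $R$ replicates has binomial noise $\sqrt{0.2 \cdot 0.8 / R}$; the
acceptance test therefore rejects only when the observed count exceeds the
one-sided 95% binomial envelope of the bound.

The test statistic is the Cox efficient score at $\beta = 0$. Without
covariates the score is linear in the activities, $U_k = \sum_i c_i
x_{ki}$, with weights $c_i = \delta_i - \hat H_0(t_i)$ depending only on
the outcome; permuting outcomes is then equivalent to permuting $c$, all
permutations collapse into one matrix product, and $U$ is normalised by
its exact permutation standard deviation. With covariates, a null Cox
model is refit per permutation and the covariate-adjusted (offset-weighted)
score test is used. The same statistic is always applied to observed and
permuted data, which is all the permutation framework requires; full
partial-likelihood Wald fits are reported by `fit_cox()` but are far too
slow to refit $10^4 \times k$ times.

## Random survival forest stratification

`surv_forest()` grows 1000 survival trees. Each tree draws exactly 5
candidate TCs (per tree, without replacement) and sees *all* patients —
there is no bootstrap — so the summed co-terminal-node proximity matrix
has diagonal exactly `n_trees`. Nodes split at the cutpoint maximising the
two-sample log-rank statistic over midpoints of consecutive distinct
activity values, subject to child minima of 15 samples and 5 events.

A split is admitted only if its maximised statistic is significant at
`split_alpha = 0.05` after Bonferroni correction over the cutpoints
evaluated in that node. This conditional-inference-style gate is what
makes the forest informative: without it, any node large enough always
finds *some* positive log-rank split, every candidate is eventually used,
and the candidacy-normalised importance score — trees using the TC in at
least one split divided by trees where it was a candidate — saturates at
1.0 for signal and noise alike. With the gate, trees on
survival-independent candidates usually stay unsplit, and a
hazard-carrying TC stands out with importance near 1 against a noise
background near the per-node false-positive rate.

Patients are stratified by Ward-D2 hierarchical clustering of the
dissimilarity $1 - \text{proximity}/n_\text{trees}$;
`select_max_subgroups()` reports the largest cluster count $k \le 10$
whose $k$-sample log-rank test is significant at $\alpha = 0.05$ (or
$k = 1$ when none is). Forest robustness across runs or input sets is
summarised by the Pearson correlation of the upper triangles of the two
final proximity matrices.

## Projection, robustness and unit-level significance

`project()` transfers a TC set to independent data: genes are intersected
(at least 50% of TC genes must be present), weights re-standardized on the
intersection, and activities re-fit by least squares. Bulk projections
gene-center the new data; single-sample input is projected uncentered
(weights have mean zero, so an intercept is absorbed).

`match_components()` matches two TC sets greedily one-to-one in
descending $|r|$ of gene weights; matches with $|r| > 0.5$ are *robust*.
`run_sensitivity()` chains the full design: decompose primary and
secondary datasets, match, project robust secondary TCs onto the held-out
survival dataset (whose samples must be disjoint from the secondary set),
re-run the survival selection, and compare the two forests' proximity
matrices.

Spatial and single-cell significance maps use a gene-label permutation
null: a unit's observed activity is compared with activities recomputed
after shuffling the pairing between weights and expression, with two-sided
add-one empirical $p$-values (floor $1/(B+1)$; 5000 permutations for
spatial spots, 3000 for cells). Unit-level projections are deliberately
*not* centered across units: the null is exchangeable against one unit's
own expression, and cross-unit centering would hand every out-of-region
spot a genuine negative alignment equal to the region's mean activity,
saturating the map. Any baseline shared by all units contributes only a
constant per-TC offset because the weights have mean zero. For single
cells, activities are first normalised by a Johnson-family transformation
(SU/SB selected by the Slifker–Shapiro quantile ratio, z-score fallback
near the lognormal boundary) fitted to each TC's pooled null, and
per-cell-type medians and quartiles are reported for box-plot rendering.
What the transformation smooths is the tail behaviour of the null — the
empirical floor of $1/(B+1)$ is replaced by the fitted parametric tail.

## The synthetic cohort and what it does (not) show

`simulate_cohort()` inverts the model with known ground truth:

* **Sources** — `n_components = 5` sparse programs over
  `n_genes = 1000`; each has `active_fraction = 0.1` (about 100 genes,
  the size of a typical curated transcriptional program) with one-sided
  exponential weights of scale 3 (super-Gaussian, excess kurtosis 6, as
  ICA assumes; sign-coherent, as programs predominantly induce their
  targets), near-zero Gaussian background elsewhere, rows standardized.
  Active sets are disjoint while capacity allows.
* **Expression** — activities i.i.d. standard normal (so $|weight| \ge 3$
  keeps its z-like reading), `noise_sd = 0.7`, i.e. a signal-to-noise
  ratio near 10 at five components. This noise level also makes the 85%
  variance rule select all five components; with essentially noiseless
  data five equal sources occasionally compress into four principal
  components at 85%.
* **Survival** — event times exponential with rate
  $\lambda_0 \exp(\sum_k \beta_k a_{ks})$, `baseline_rate = 0.02`/month,
  independent exponential censoring at `censor_rate = 0.01`/month
  (roughly two-thirds events), clinical covariates drawn from realistic
  early-CRC frequencies including explicit `"unknown"` levels.
* **Gene sets** — one planted set per component (its active genes in
  descending weight order, 10–100 genes) plus uniform null sets.
* **Spatial profiles** — a grid of spots with one component's activity
  set to `boost` inside a region mask and 0 outside, other activities
  standard normal.

The generator reproduces the *statistical* structure every stage assumes —
linear mixing, super-Gaussian sparse sources, proportional hazards,
exchangeable nulls. It does not emulate probe-level measurement, batch
effects, correlated or overlapping programs, non-proportional hazards, or
spatial autocorrelation of noise; passing tests demonstrate correctness of
the machinery under the model, not performance on any real cohort.

## Numerical choices and degenerate inputs

* ICA: tolerance $10^{-6}$ on the symmetric-decorrelation update, at most
  1000 iterations; non-convergence is an error naming the run seed (or a
  warning with `on_nonconvergence = "warn"` — Gaussian-only data is
  unidentifiable for ICA and flagged this way rather than silently
  accepted).
* Constant matrices, constant activities, empty masks, empty retained
  component sets, rank-deficient weight matrices and mismatched sample
  sets are explicit errors; collinear components are named.
* Problem sizes in the test suite: the shared fixture uses 400 genes,
  3 sources and 120 samples; the acceptance suite runs the full stated
  conditions (1000 genes, 300–400 samples, 25 runs, 1000 trees, 1000
  permutations, 50–200 replicates).
* Permutation $p$-values carry the add-one correction and are bounded
  below by $1/(B+1)$.
* All stage seeds derive deterministically from one master seed; outputs
  are plain text and byte-reproducible, verified by md5 manifests.

## Known limitations

* Correlated sources violate ICA's independence assumption; recovery
  degrades gracefully but credibility indices, not warnings, are the
  diagnostic.
* The Welch-Z null is approximate for extremely sparse weight profiles
  (see above).
* The importance score is a candidacy-normalised usage fraction; other
  RSF importance definitions (minimal depth, permutation importance) are
  out of scope.
* The forest does not predict individual survival curves and has no
  out-of-bag machinery; it is used solely for proximity stratification
  and importance, per the analysis design.
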