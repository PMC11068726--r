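# Shared fixtures, built once per test run. Kept deliberately small: the
# full-scale study conditions live in test-acceptance.R.

fixture_env <- new.env(parent = emptyenv())

# small cohort: 3 sources, 400 genes, 120 samples, SNR ~ 10
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- simulate_cohort(
      n_genes = 400, n_components = 3, n_samples = 120,
      active_fraction = 0.1, noise_sd = sqrt(3 / 10),
      hazard_betas = c(1, 0, 0), n_null_sets = 30, seed = 421)
  }
  fixture_env$small
}

small_fit <- function() {
  if (is.null(fixture_env$fit)) {
    fixture_env$fit <- cica(small_cohort()$expression, n_runs = 10,
                            seed = 77)
  }
  fixture_env$fit
}

# adjusted Rand index between two labelings (permutation-invariant)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# greedy matching of fitted components to true sources; returns the mean and
# per-source best |r| and the matched row order
match_to_truth <- function(fitted_weights, true_weights) {
  R <- abs(cor(t(fitted_weights), t(true_weights)))
  best <- apply(R, 2, max)
  list(mean_r = mean(best), per_source = best,
       order = apply(R, 2, which.max))
}
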