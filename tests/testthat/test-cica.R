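# Consensus ICA: component-count selection, single-run source recovery,
# cross-run clustering with the one-per-run cap, consensus credibility
# arithmetic, mixing estimation and reconstruction bookkeeping.

test_that("select_n_components follows the cumulative-variance rule", {
  # rank-1: all samples proportional to one profile
  g <- sprintf("g%03d", 1:50)
  base <- rnorm(50)
  X1 <- outer(base, c(1, 2, -1, 0.5, 3))
  dimnames(X1) <- list(g, paste0("s", 1:5))
  expect_equal(select_n_components(X1), 1L)
  # ten orthogonal equal-variance directions: 8/10 < 0.85 <= 9/10
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(100 * 10), 100, 10)))     # orthonormal loadings
  V <- qr.Q(qr(cbind(1, matrix(rnorm(12 * 10), 12, 10))))[, 2:11]
  X2 <- Q %*% (5 * t(V))          # columns of V are orthogonal to the mean
  dimnames(X2) <- list(sprintf("g%03d", 1:100), paste0("s", 1:12))
  expect_equal(select_n_components(X2, 0.85), 9L)
  # constant matrix: zero total variance
  X3 <- matrix(2, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  expect_error(select_n_components(X3), "zero total variance")
})

test_that("single ICA run separates a two-source zero-noise mixture", {
  truth <- generate_sources(500, 2, 0.1, seed = 11)
  mix <- generate_expression(truth, 60, noise_sd = 0, seed = 12)
  run <- run_single_ica(mix$expression, 2, seed = 13)
  m <- match_to_truth(run$components, truth$weights)
  expect_true(all(m$per_source > 0.999))
  run2 <- run_single_ica(mix$expression, 2, seed = 13)
  expect_identical(run$components, run2$components)
  expect_error(run_single_ica(mix$expression, 2, seed = 13, max_iter = 1),
               "seed 13")
  expect_warning(run_single_ica(mix$expression, 2, seed = 13, max_iter = 1,
                                on_nonconvergence = "warn"),
                 "did not converge")
  expect_error(run_single_ica(mix$expression, 100, seed = 1), "exceeds")
})

test_that("cross-run clustering respects sign, threshold and the run cap", {
  set.seed(21)
  comp <- matrix(rnorm(3 * 200), 3, 200)
  comp <- comp / apply(comp, 1, sd)
  # two runs, second with flipped signs: clusters of size 2, opposite signs
  runs <- list(list(components = comp), list(components = -comp))
  cl <- cluster_components(runs, r_threshold = 0.9)
  expect_length(cl, 3)
  for (c1 in cl) {
    expect_equal(nrow(c1$members), 2)
    expect_equal(sort(c1$members$sign), c(-1L, 1L))
  }
  # sub-threshold correlation: all singletons
  set.seed(22)
  lowr <- list(list(components = comp),
               list(components = matrix(rnorm(3 * 200), 3, 200)))
  expect_length(cluster_components(lowr, r_threshold = 0.9), 6)
  # many identical runs: cluster sizes capped at the number of runs
  runs25 <- rep(list(list(components = comp)), 25)
  cl25 <- cluster_components(runs25, r_threshold = 0.9)
  expect_length(cl25, 3)
  expect_true(all(vapply(cl25, function(x) nrow(x$members), 1L) == 25))
  # credibility is invariant to run order
  perm <- sample(25)
  sizes <- function(cl) sort(vapply(cl, function(x) nrow(x$members), 1L))
  expect_identical(sizes(cluster_components(runs25[perm])), sizes(cl25))
})

test_that("consensus credibility arithmetic and retention are exact", {
  set.seed(31)
  v <- rnorm(100)
  mk_cluster <- function(size) list(
    members = data.frame(run = seq_len(size), component = 1L,
                         sign = 1L),
    consensus = v + rnorm(100, sd = 0.01))
  clusters <- list(mk_cluster(25), mk_cluster(13), mk_cluster(12))
  tcs <- build_consensus(clusters, n_runs = 25, credibility_threshold = 0.5)
  expect_equal(unname(tcs$credibility), c(1.00, 0.52))   # 12/25 dropped
  expect_equal(nrow(tcs$weights), 2)
  expect_equal(unname(rowMeans(tcs$weights)), c(0, 0), tolerance = 1e-12)
  expect_error(build_consensus(list(mk_cluster(5)), n_runs = 25),
               "credibility threshold")
})

test_that("mixing estimation is exact least squares with safe degenerate cases", {
  set.seed(41)
  S <- matrix(rnorm(3 * 300), 3, 300,
              dimnames = list(paste0("TC", 1:3), sprintf("g%03d", 1:300)))
  S <- S - rowMeans(S)
  S <- S / apply(S, 1, sd)
  tcs <- tcset(S, standardize = FALSE)
  A <- matrix(rnorm(3 * 7), 3, 7)
  A <- cbind(A - rowMeans(A), 0)              # gene means zero, sample 8 silent
  X <- crossprod(S, A)
  dimnames(X) <- list(colnames(S), paste0("s", 1:8))
  A_tgt <- estimate_mixing(X, tcs)
  expect_equal(unname(A_tgt), unname(A), tolerance = 1e-8)
  expect_equal(unname(A_tgt[, 8]), rep(0, 3), tolerance = 1e-8)
  # collinear components are named in the error
  Sbad <- rbind(S, TC4 = S[1, ])
  expect_error(estimate_mixing(X, tcset(Sbad, standardize = FALSE)),
               "collinear")
})

test_that("reconstruction reports faithful R-squared", {
  truth <- generate_sources(300, 3, 0.1, seed = 51)
  mix <- generate_expression(truth, 40, noise_sd = 0, seed = 52)
  A <- estimate_mixing(mix$expression, truth)
  rec <- reconstruct(truth, A, mix$expression)
  expect_gt(rec$r2_overall, 0.999)
  zero <- reconstruct(truth, matrix(0, 3, 2,
                                    dimnames = list(rownames(truth$weights),
                                                    c("a", "b"))))
  expect_true(all(zero$values == 0))
  expect_error(reconstruct(truth, A[-1, , drop = FALSE]), "component ids")
})

test_that("cica recovers planted sources with full credibility", {
  sim <- small_cohort()
  fit <- small_fit()
  m <- match_to_truth(fit$components$weights, sim$truth$weights)
  expect_gte(m$mean_r, 0.95)
  expect_equal(unname(fit$credibility), rep(1, 3))
  # recovered activities track the true mixing matrix
  for (k in 1:3)
    expect_gt(abs(cor(fit$mixing[m$order[k], ], sim$mixing[k, ])), 0.95)
  # near-orthogonality of distinct consensus components
  cc <- cor(t(fit$components$weights))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)
  expect_gte(fit$r2_overall, 0.85)
})

test_that("cica is deterministic and well-defined for a single run", {
  sim <- small_cohort()
  f1 <- cica(sim$expression, n_runs = 10, seed = 77)
  expect_identical(f1$components$weights, small_fit()$components$weights)
  expect_identical(f1$mixing, small_fit()$mixing)
  f2 <- cica(sim$expression, n_runs = 1, seed = 5)
  expect_true(all(f2$credibility == 1))              # singletons, 1/1 runs
})

test_that("cica methods expose the model components coherently", {
  sim <- small_cohort()
  fit <- small_fit()
  expect_identical(coef(fit), fit$mixing)
  pr <- predict(fit, sim$expression)
  for (k in seq_len(nrow(pr)))
    expect_gt(cor(pr[k, ], fit$mixing[k, ]), 0.99)
  expect_equal(fitted(fit) + residuals(fit), sim$expression,
               tolerance = 1e-10)
  expect_output(print(fit), "Consensus ICA")
  expect_output(print(summary(fit)), "credibility")
})
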