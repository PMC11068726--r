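# Random survival forest: log-rank splitting against closed-form and
# survdiff oracles, tree and forest determinism, proximity bookkeeping,
# importance discrimination and proximity-based stratification.

mk_surv <- function(time, event, ids = paste0("s", seq_along(time))) {
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("logrank_split reproduces the textbook two-group statistic", {
  # 4 samples, times 1..4, all events, perfect value split {0,0} vs {1,1}:
  # O1 = 2, E1 = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36 -> chi2 = 49/17
  sv <- mk_surv(1:4, rep(1, 4))
  res <- logrank_split(c(0, 0, 1, 1), sv, min_node_size = 2,
                       min_node_events = 1, split_alpha = 1)
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(res$cutpoint, 0.5)
  # survdiff oracle on the same dichotomy
  sd_ <- survival::survdiff(survival::Surv(sv$time, sv$event) ~
                              c(0, 0, 1, 1))
  expect_equal(res$statistic, sd_$chisq, tolerance = 1e-12)
})

test_that("logrank_split matches survdiff at its chosen cutpoint", {
  set.seed(71)
  n <- 60
  x <- rnorm(n)
  sv <- mk_surv(rexp(n, 0.05 * exp(0.8 * (x > 0))), rbinom(n, 1, 0.8))
  res <- logrank_split(x, sv, min_node_size = 5, min_node_events = 2,
                       split_alpha = 1)
  grp <- x <= res$cutpoint
  sd_ <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ grp)
  expect_equal(res$statistic, sd_$chisq, tolerance = 1e-10)
})

test_that("logrank_split returns NULL for degenerate nodes", {
  sv <- mk_surv(1:10, rep(1, 10))
  expect_null(logrank_split(rep(2, 10), sv, min_node_size = 2,
                            min_node_events = 1, split_alpha = 1))
  expect_null(logrank_split(rnorm(10), sv, min_node_size = 6,
                            min_node_events = 1, split_alpha = 1))
  # identical survival in both halves: statistic 0, no split
  sv2 <- mk_surv(c(1, 2, 3, 4, 1, 2, 3, 4), rep(1, 8))
  expect_null(logrank_split(c(0, 0.1, 0, 0.1, 1, 1.1, 1, 1.1), sv2,
                            min_node_size = 1, min_node_events = 1,
                            split_alpha = 1))
})

test_that("grow_tree splits on a perfectly separating component", {
  set.seed(81)
  n <- 120
  A <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("TC", 1:3), paste0("s", 1:n)))
  grp <- A[2, ] > 0
  sv <- mk_surv(rexp(n, 0.02 * exp(2.5 * grp)), rep(1, n))
  tree <- grow_tree(A, sv, paste0("TC", 1:3))
  expect_equal(tree$nodes$split_tc[1], "TC2")
  expect_identical(grow_tree(A, sv, paste0("TC", 1:3))$nodes, tree$nodes)
  # terminal nodes partition the samples
  expect_true(all(table(tree$terminal) >= 1))
  expect_length(tree$terminal, n)
  expect_error(grow_tree(A, sv, "TC9"), "absent")
})

test_that("trees on survival-independent data usually stay unsplit", {
  unsplit <- vapply(1:10, function(r) {
    set.seed(900 + r)
    n <- 100
    A <- matrix(rnorm(3 * n), 3, n,
                dimnames = list(paste0("TC", 1:3), paste0("s", 1:n)))
    sv <- mk_surv(rexp(n, 0.05), rbinom(n, 1, 0.8))
    tree <- grow_tree(A, sv, paste0("TC", 1:3))
    all(is.na(tree$nodes$split_tc))
  }, TRUE)
  expect_gte(mean(unsplit), 0.5)
})

test_that("forest proximity satisfies its counting invariants", {
  sim <- small_cohort()
  f <- surv_forest(sim$mixing, sim$survival, n_trees = 50, tcs_per_tree = 2,
                   seed = 2)
  P <- final_proximity(f)
  expect_true(all(diag(P) == 50))
  expect_identical(P, t(P))
  expect_true(all(P >= 0 & P <= 50))
  expect_error(surv_forest(sim$mixing, sim$survival, tcs_per_tree = 10),
               "fewer components")
  # a forest of unsplittable trees gives all-ones per-tree proximity
  tiny <- sim$survival[1:20, ]
  Atiny <- sim$mixing[, 1:20]
  f1 <- surv_forest(Atiny, tiny, n_trees = 2, tcs_per_tree = 2,
                    min_node_size = 15, seed = 3)
  expect_true(all(final_proximity(f1) == 2))
})

test_that("relabeling samples permutes the proximity matrix equivariantly", {
  sim <- small_cohort()
  f <- surv_forest(sim$mixing, sim$survival, n_trees = 30, tcs_per_tree = 2,
                   seed = 4)
  pr <- sample(ncol(sim$mixing))
  A2 <- sim$mixing[, pr]
  sv2 <- sim$survival[pr, ]
  f2 <- surv_forest(A2, sv2, n_trees = 30, tcs_per_tree = 2, seed = 4)
  expect_equal(final_proximity(f2),
               final_proximity(f)[colnames(A2), colnames(A2)])
})

test_that("importance scores are bounded and single out the causal component", {
  set.seed(91)
  n <- 250; k <- 10
  A <- matrix(rnorm(k * n), k, n,
              dimnames = list(paste0("TC", 1:k), paste0("s", 1:n)))
  grp <- as.integer(A[4, ] > median(A[4, ]))
  sv <- generate_survival(matrix(grp, 1, n,
                                 dimnames = list("g", colnames(A))),
                         1.2, baseline_rate = 0.02, censor_rate = 0.01,
                         seed = 92)
  f <- surv_forest(A, sv, n_trees = 300, tcs_per_tree = 3, seed = 93)
  imp <- importance_scores(f)
  expect_true(all(imp >= 0 & imp <= 1))
  expect_equal(names(which.max(imp)), "TC4")
})

test_that("proximity clustering recovers block structure exactly", {
  n <- 40
  P <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  blocks <- rep(1:2, each = n / 2)
  P[blocks == 1, blocks == 1] <- 100
  P[blocks == 2, blocks == 2] <- 100
  lab <- cluster_proximity(P, 2, n_trees = 100)
  expect_equal(ari(lab, blocks), 1)
  labn <- cluster_proximity(P, n, n_trees = 100)
  expect_length(unique(labn), n)
  expect_error(cluster_proximity(P, n + 1, n_trees = 100), "exceeds")
  expect_error(cluster_proximity(P, 1, n_trees = 100), ">= 2")
})

test_that("select_max_subgroups scans k by log-rank significance", {
  set.seed(95)
  n <- 60
  blocks <- rep(1:2, each = n / 2)
  P <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  P[blocks == 1, blocks == 1] <- 100
  P[blocks == 2, blocks == 2] <- 100
  # survival identical across clusters: no significant split
  sv_null <- mk_surv(rep(rexp(n / 2, 0.05), 2), rep(1, n),
                     ids = paste0("s", 1:n))
  res0 <- select_max_subgroups(P, sv_null, k_max = 5, n_trees = 100)
  expect_equal(res0$k, 1L)
  # strongly separated hazards: at least the 2-group split is found
  sv_sig <- mk_surv(rexp(n, 0.02 * exp(2 * (blocks == 2))), rep(1, n),
                    ids = paste0("s", 1:n))
  res1 <- select_max_subgroups(P, sv_sig, k_max = 5, n_trees = 100)
  expect_gte(res1$k, 2L)
  expect_equal(ari(cluster_proximity(P, 2, 100), blocks), 1)
  # alpha = 1 accepts every k
  res2 <- select_max_subgroups(P, sv_sig, k_max = 5, alpha = 1,
                               n_trees = 100)
  expect_equal(res2$k, 5L)
})

test_that("compare_proximity correlates off-diagonal structure", {
  sim <- small_cohort()
  f <- surv_forest(sim$mixing, sim$survival, n_trees = 40, tcs_per_tree = 2,
                   seed = 6)
  P <- final_proximity(f)
  expect_equal(compare_proximity(P, P), 1)
  set.seed(7)
  pr <- sample(nrow(P))
  Pshuf <- P[pr, pr]
  dimnames(Pshuf) <- dimnames(P)              # break the pairing
  expect_lt(abs(compare_proximity(P, Pshuf)), 0.3)
  expect_error(compare_proximity(P, P[-1, -1]), "different sample sets")
})
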