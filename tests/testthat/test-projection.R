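# Cross-dataset projection, component matching, permutation activity
# significance and the Johnson SU normalisation.

test_that("projection reproduces training activities and is linear", {
  sim <- small_cohort()
  fit <- small_fit()
  A <- project(fit$components, sim$expression)
  for (k in seq_len(nrow(A)))
    expect_gt(cor(A[k, ], fit$mixing[k, ]), 0.99)
  expect_equal(attr(A, "overlap"), 1)
  # linearity on shared genes
  X <- sim$expression
  set.seed(1)
  Y <- X + matrix(rnorm(length(X)), nrow(X), ncol(X))
  pa <- project(fit$components, 2 * X - 3 * Y)
  ref <- 2 * project(fit$components, X) - 3 * project(fit$components, Y)
  expect_equal(unname(pa), unname(ref), tolerance = 1e-8)
})

test_that("projection handles single samples and enforces gene overlap", {
  sim <- small_cohort()
  tcs <- sim$truth
  one <- matrix(tcs$weights[2, ], ncol = 1,
                dimnames = list(colnames(tcs$weights), "probe"))
  a <- project(tcs, one)
  expect_equal(names(which.max(abs(a[, 1]))), "S2")
  zero <- matrix(0, nrow(one), 1,
                 dimnames = list(rownames(one), "null"))
  expect_equal(unname(project(tcs, zero)[, 1]), rep(0, 3), tolerance = 1e-10)
  few <- sim$expression[1:100, ]
  expect_error(project(tcs, few), "overlap")
})

test_that("match_components pairs components one-to-one by |r|", {
  sim <- small_cohort()
  tcs <- sim$truth
  flipped <- tcset(-tcs$weights, standardize = FALSE)
  m <- match_components(tcs, flipped)
  expect_equal(nrow(m), 3)
  expect_true(all(abs(abs(m$r) - 1) < 1e-12))
  expect_true(all(m$robust))
  expect_equal(anyDuplicated(m$secondary), 0)
  # independent random vectors: no robust matches
  set.seed(12)
  rand <- tcset(matrix(rnorm(3 * ncol(tcs$weights)), 3,
                       dimnames = list(paste0("R", 1:3),
                                       colnames(tcs$weights))))
  m2 <- match_components(tcs, rand)
  expect_false(any(m2$robust))
  # lowering the threshold never reduces the robust count
  expect_gte(sum(match_components(tcs, rand, r_threshold = 0.01)$robust),
             sum(m2$robust))
})

test_that("permutation significance maps localized activity", {
  truth <- generate_sources(400, 3, 0.1, seed = 31)
  mask <- matrix(FALSE, 8, 8); mask[3:5, 3:5] <- TRUE
  sp <- generate_spatial_profile(truth, c(8, 8), mask, "S1", boost = 3,
                                 noise_sd = 0.1, seed = 32)
  m <- permutation_activity_significance(truth, sp, n_perm = 400, seed = 33)
  expect_true(all(m$p_value >= 1 / 401 & m$p_value <= 1))
  m1 <- m[m$tc_id == "S1", ]
  inside <- mask[cbind(m1$row, m1$col)]
  expect_gt(median(m1$neg_log10_p[inside]), median(m1$neg_log10_p[!inside]))
  expect_warning(
    permutation_activity_significance(truth, sp, n_perm = 50, seed = 1),
    "coarse")
})

test_that("permutation p-values are uniform on pure-noise profiles", {
  truth <- generate_sources(400, 3, 0.1, seed = 41)
  set.seed(42)
  noise <- matrix(rnorm(400 * 250), 400, 250,
                  dimnames = list(colnames(truth$weights),
                                  paste0("u", 1:250)))
  m <- permutation_activity_significance(truth, noise, n_perm = 400,
                                         seed = 43)
  ks <- suppressWarnings(stats::ks.test(m$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Johnson-family fit normalises skewed null distributions", {
  # exact SU sample: fitting recovers a transform that re-normalises it
  set.seed(51)
  z <- rnorm(8000)
  x_su <- 2 + 1.5 * sinh((z - 0.8) / 1.2)
  f <- fit_johnson_su(x_su)
  expect_equal(attr(f, "params")$family, "SU")
  expect_gt(suppressWarnings(stats::ks.test(f(x_su), "pnorm"))$p.value, 0.01)
  # bounded positively skewed sample selects the SB branch and improves
  x_sb <- rexp(8000)
  g <- fit_johnson_su(x_sb)
  expect_equal(attr(g, "params")$family, "SB")
  ks_raw <- suppressWarnings(stats::ks.test(scale(x_sb), "pnorm"))$statistic
  ks_fit <- suppressWarnings(stats::ks.test(g(x_sb), "pnorm"))$statistic
  expect_lt(ks_fit, ks_raw)
  expect_true(all(diff(g(sort(x_sb))) >= 0))          # monotone
  # near-normal input keeps a near-identity z-scale
  y <- rnorm(5000)
  h <- fit_johnson_su(y)
  expect_gt(cor(h(y), y), 0.999)
})

test_that("single-cell projection ranks the planted cell type highest", {
  truth <- generate_sources(400, 3, 0.1, seed = 61)
  mix <- generate_expression(truth, 300, noise_sd = 0.3, seed = 62)
  X <- mix$expression
  labels <- rep(c("epithelial", "stromal", "immune"), each = 100)
  boost_genes <- attr(truth, "active_genes")$S3
  X[boost_genes, labels == "stromal"] <-
    X[boost_genes, labels == "stromal"] + 2
  res <- single_cell_activity(truth, X, labels, n_perm = 200,
                              subsample_fraction = 0.5, seed = 63)
  b3 <- res$by_label[res$by_label$tc_id == "S3", ]
  expect_equal(b3$label[which.max(b3$median)], "stromal")
  # full subsample is deterministic and covers every cell
  res1 <- single_cell_activity(truth, X, labels, n_perm = 50,
                               subsample_fraction = 1, seed = 64)
  res2 <- single_cell_activity(truth, X, labels, n_perm = 50,
                               subsample_fraction = 1, seed = 64)
  expect_identical(res1$cells, res2$cells)
  expect_equal(length(unique(res1$cells$cell_id)), 300)
  # tiny cell types are excluded with a warning
  lab2 <- c(rep("big", 298), "rare", "rare")
  expect_warning(single_cell_activity(truth, X, lab2, n_perm = 20,
                                      subsample_fraction = 1, seed = 65),
                 "rare")
})
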