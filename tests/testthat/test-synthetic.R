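# Ground-truth generators: dimensional contracts, seed determinism, the
# zero-noise reconstruction identity and survival-model calibration.

test_that("generate_sources honors sparsity, disjointness and standardization", {
  truth <- generate_sources(1000, 5, 0.02, seed = 1)
  expect_equal(dim(truth$weights), c(5, 1000))
  active <- attr(truth, "active_genes")
  expect_true(all(lengths(active) == 20))
  expect_equal(anyDuplicated(unlist(active)), 0)      # capacity allows disjoint
  expect_equal(unname(rowMeans(truth$weights)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(truth$weights, 1, sd)), rep(1, 5),
               tolerance = 1e-9)
  expect_identical(truth$weights, generate_sources(1000, 5, 0.02, seed = 1)$weights)
  expect_error(generate_sources(10, 10, 0.1, seed = 1), "smaller")
  expect_error(generate_sources(100, 2, 1.2, seed = 1), "active_fraction")
})

test_that("active sets are reused minimally when capacity is exceeded", {
  truth <- generate_sources(100, 4, 0.5, seed = 3)
  active <- attr(truth, "active_genes")
  expect_true(all(lengths(active) == 50))
  expect_equal(length(unique(unlist(active))), 100)   # every gene used
})

test_that("generate_expression satisfies the zero-noise identity", {
  truth <- generate_sources(200, 3, 0.1, seed = 2)
  mix <- generate_expression(truth, 20, noise_sd = 0, seed = 5)
  expect_equal(mix$expression,
               crossprod(truth$weights, mix$mixing), tolerance = 1e-12)
  # rank-1: one component, each sample column is activity times the weights
  t1 <- generate_sources(200, 1, 0.1, seed = 2)
  m1 <- generate_expression(t1, 5, noise_sd = 0, seed = 6)
  for (j in 1:5)
    expect_equal(unname(m1$expression[, j]),
                 unname(m1$mixing[1, j] * t1$weights[1, ]), tolerance = 1e-12)
  expect_error(generate_expression(truth, 20, noise_sd = -1), "non-negative")
  expect_error(generate_expression(truth, 4), "n_samples")
})

test_that("sample covariance spectrum has k dominant eigenvalues", {
  truth <- generate_sources(1000, 5, 0.1, seed = 1)
  mix <- generate_expression(truth, 200, activity_sd = 1, noise_sd = 0.1,
                             seed = 7)
  Xc <- mix$expression - rowMeans(mix$expression)
  ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[5] / ev[6], 50)                        # clear spectral gap
})

test_that("generate_survival matches its null and symmetric special cases", {
  truth <- generate_sources(200, 3, 0.1, seed = 4)
  mix <- generate_expression(truth, 2000, noise_sd = 0, seed = 4)
  # no censoring, no effect: all events, exponential(baseline) times
  s0 <- generate_survival(mix$mixing, c(0, 0, 0), baseline_rate = 0.05,
                          censor_rate = 0, seed = 1)
  expect_equal(mean(s0$event), 1)
  expect_equal(mean(s0$time), 20, tolerance = 0.1 * 20)
  # equal event and censoring rates: event fraction 1/2
  s1 <- generate_survival(mix$mixing, c(0, 0, 0), baseline_rate = 0.03,
                          censor_rate = 0.03, seed = 2)
  expect_equal(mean(s1$event), 0.5, tolerance = 0.05)
  # positive hazard coefficient shortens observed times
  s2 <- generate_survival(mix$mixing, c(1, 0, 0), baseline_rate = 0.02,
                          censor_rate = 0.01, seed = 3)
  expect_lt(cor(mix$mixing[1, ], s2$time, method = "spearman"), -0.3)
  expect_error(generate_survival(mix$mixing, c(0, 0, 0), baseline_rate = 0),
               "positive")
  expect_setequal(setdiff(names(s2), c("sample_id", "time", "event")),
                  c("sex", "stage", "location", "adjuvant", "msi", "braf",
                    "kras"))
  expect_true("unknown" %in% s2$msi)
})

test_that("null survival generator is calibrated for Cox inference", {
  truth <- generate_sources(100, 2, 0.1, seed = 9)
  covered <- vapply(1:100, function(r) {
    mix <- generate_expression(truth, 80, noise_sd = 0, seed = 1000 + r)
    sv <- generate_survival(mix$mixing, c(0, 0), baseline_rate = 0.03,
                            censor_rate = 0.015, seed = 2000 + r)
    fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ mix$mixing[1, ])
    ci <- exp(confint(fit))
    ci[1] <= 1 && ci[2] >= 1
  }, TRUE)
  expect_gte(mean(covered), 0.88)                     # nominal 95% coverage
})

test_that("generate_gene_sets plants and sizes sets as configured", {
  truth <- generate_sources(1000, 5, 0.1, seed = 5)
  gs <- generate_gene_sets(truth, n_null_sets = 30, seed = 6)
  expect_length(gs, 35)                               # 5 planted + 30 null
  expect_length(grep("^planted_", names(gs)), 5)
  fixed <- generate_gene_sets(truth, n_null_sets = 10,
                              set_size_range = c(10, 10), seed = 7)
  expect_true(all(lengths(fixed) == 10))
  expect_error(generate_gene_sets(truth, set_size_range = c(5, 100)),
               "\\[10, 500\\]")
  expect_error(generate_gene_sets(truth, set_size_range = c(10, 600)),
               "\\[10, 500\\]")
})

test_that("spatial generator plants a localized activity region", {
  truth <- generate_sources(400, 3, 0.1, seed = 8)
  mask <- matrix(FALSE, 8, 8); mask[2:5, 2:5] <- TRUE
  sp <- generate_spatial_profile(truth, c(8, 8), mask, "S2", boost = 5,
                                 noise_sd = 0.1, seed = 9)
  expect_equal(ncol(sp), 64)
  coords <- attr(sp, "coordinates")
  A <- attr(sp, "true_mixing")
  inside <- mask[cbind(coords$row, coords$col)]
  expect_true(all(A["S2", inside] == 5) && all(A["S2", !inside] == 0))
  # boost 0 leaves no contrast in the boosted component
  sp0 <- generate_spatial_profile(truth, c(8, 8), mask, "S2", boost = 0,
                                  noise_sd = 0.1, seed = 9)
  A0 <- attr(sp0, "true_mixing")
  expect_true(all(A0["S2", ] == 0))
  # all-spot mask: boosted activity constant everywhere, no spatial contrast
  spfull <- generate_spatial_profile(truth, c(8, 8),
                                     matrix(TRUE, 8, 8), "S2", boost = 3,
                                     noise_sd = 0, seed = 9)
  expect_equal(unname(attr(spfull, "true_mixing")["S2", ]), rep(3, 64))
  expect_error(generate_spatial_profile(truth, c(8, 8),
                                        matrix(FALSE, 8, 8), "S2"),
               "at least one spot")
  expect_error(generate_spatial_profile(truth, c(8, 8), matrix(TRUE, 4, 4),
                                        "S2"), "match")
})

test_that("simulate_cohort is reproducible and internally consistent", {
  sim <- small_cohort()
  expect_identical(colnames(sim$expression), sim$survival$sample_id)
  expect_identical(colnames(sim$expression), colnames(sim$mixing))
  expect_true(all(sim$subgroups %in% 1:2))
  sim2 <- simulate_cohort(n_genes = 400, n_components = 3, n_samples = 120,
                          active_fraction = 0.1, noise_sd = sqrt(3 / 10),
                          hazard_betas = c(1, 0, 0), n_null_sets = 30,
                          seed = 421)
  expect_identical(sim$expression, sim2$expression)
  expect_identical(sim$survival, sim2$survival)
})
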