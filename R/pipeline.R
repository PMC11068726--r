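# End-to-end orchestration: configuration handling, the full synthetic
# pipeline (simulate -> decompose -> enrich -> survival -> forest ->
# project) with a reproducible file manifest, and the split-dataset
# sensitivity analysis.

#' Default pipeline configuration
#'
#' Stage parameters default to the method's canonical settings (25 ICA runs,
#' 85% variance, |r| > 0.9 clustering, credibility 0.5, 10000 survival
#' permutations at FDR 5% / 80% confidence, 1000 trees with 5 components per
#' tree, 5000 spatial and 3000 single-cell permutations); the simulate block
#' defaults to a reduced desk-scale cohort. Every stage can be toggled.
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, decompose = TRUE, enrich = TRUE,
                  survival = TRUE, forest = TRUE, project = TRUE),
    simulate = list(n_genes = 1000L, n_components = 5L, n_samples = 300L,
                    active_fraction = 0.1, noise_sd = 0.7,
                    baseline_rate = 0.02, censor_rate = 0.01,
                    n_null_sets = 50L),
    decompose = list(n_runs = 25L, variance_threshold = 0.85,
                     r_threshold = 0.9, credibility_threshold = 0.5),
    enrich = list(alpha = 0.05, min_size = 10L, max_size = 500L),
    survival = list(n_perm = 10000L, fdr = 0.05, confidence = 0.8,
                    covariates = c("sex", "msi", "braf", "kras", "location",
                                   "stage", "adjuvant")),
    forest = list(n_trees = 1000L, tcs_per_tree = 5L, min_node_size = 15L,
                  min_node_events = 5L, split_alpha = 0.05, k_max = 10L,
                  alpha = 0.05),
    project = list(n_perm = 5000L, sc_n_perm = 3000L,
                   subsample_fraction = 0.1, r_threshold = 0.5,
                   min_overlap = 0.5)
  )
}

#' Save / load a pipeline configuration (YAML)
#'
#' Round-trips losslessly: `load_config(save_config(cfg, f))` equals `cfg`.
#'
#' @param config configuration list.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# md5 manifest over a fixed file order
build_manifest <- function(dir, files) {
  sums <- tools::md5sum(file.path(dir, files))
  data.frame(file = files, md5 = unname(sums), stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the enabled stages in order (simulate, decompose, enrich,
#' survival, forest, project), derives every stage seed deterministically
#' from the master seed, writes all artifacts as plain-text files under
#' `out_dir` and returns a run report with parameter echoes, per-stage
#' counts and an md5 file manifest. Identical configuration and seed yield a
#' byte-identical manifest.
#'
#' @param config configuration list (see [default_config]).
#' @param out_dir output directory (created if missing).
#' @return run report list: `counts`, `manifest`, `params`, `timings_s`.
#' @export
run_full <- function(config = default_config(), out_dir = tempfile("tcrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  counts <- list(); timings <- list(); files <- character(0)
  tic <- function() proc.time()[["elapsed"]]
  stage_on <- function(nm) isTRUE(config$stages[[nm]])

  sim <- fit <- NULL
  if (stage_on("simulate")) {
    t0 <- tic()
    sc <- config$simulate
    sim <- simulate_cohort(n_genes = sc$n_genes,
                           n_components = sc$n_components,
                           n_samples = sc$n_samples,
                           active_fraction = sc$active_fraction,
                           noise_sd = sc$noise_sd,
                           baseline_rate = sc$baseline_rate,
                           censor_rate = sc$censor_rate,
                           n_null_sets = sc$n_null_sets,
                           seed = seed)
    write_expression_tsv(sim$expression, file.path(out_dir, "expression.tsv"))
    write_survival_csv(sim$survival, file.path(out_dir, "survival.csv"))
    write_gmt(sim$gene_sets, file.path(out_dir, "gene_sets.gmt"))
    files <- c(files, "expression.tsv", "survival.csv", "gene_sets.gmt")
    counts$n_genes <- nrow(sim$expression)
    counts$n_samples <- ncol(sim$expression)
    timings$simulate <- tic() - t0
  }
  if (stage_on("decompose")) {
    t0 <- tic()
    dc <- config$decompose
    fit <- cica(sim$expression, n_runs = dc$n_runs,
                variance_threshold = dc$variance_threshold,
                r_threshold = dc$r_threshold,
                credibility_threshold = dc$credibility_threshold,
                seed = seed + 10L)
    write_tcset(fit$components, file.path(out_dir, "components.tsv"),
                params = c(dc, seed = seed + 10L))
    write.table(data.frame(component_id = rownames(fit$mixing), fit$mixing,
                           check.names = FALSE),
                file.path(out_dir, "mixing.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, "components.tsv", "components.tsv.json", "mixing.tsv")
    counts$n_tcs <- nrow(fit$components$weights)
    counts$r2_overall <- fit$r2_overall
    timings$decompose <- tic() - t0
  }
  if (stage_on("enrich")) {
    t0 <- tic()
    ec <- config$enrich
    coll <- filter_gene_sets(sim$gene_sets, rownames(sim$expression),
                             ec$min_size, ec$max_size)
    et <- enrichment_table(fit$components, coll, alpha = ec$alpha)
    write.table(et, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, "enrichment.tsv")
    counts$n_enriched <- sum(et$bonferroni_significant)
    timings$enrich <- tic() - t0
  }
  sel <- NULL
  if (stage_on("survival")) {
    t0 <- tic()
    sv <- config$survival
    uni <- permutation_fdr_select(fit$mixing, sim$survival,
                                  covariates = character(),
                                  n_perm = sv$n_perm, fdr = sv$fdr,
                                  confidence = sv$confidence,
                                  seed = seed + 20L)
    mult <- permutation_fdr_select(fit$mixing, sim$survival,
                                   covariates = sv$covariates,
                                   n_perm = sv$n_perm, fdr = sv$fdr,
                                   confidence = sv$confidence,
                                   seed = seed + 21L)
    sel <- combine_selections(uni, mult)
    cox <- do.call(rbind, lapply(rownames(fit$mixing), function(id)
      fit_cox(fit$mixing[id, ], sim$survival, tc_id = id)))
    write.table(cox, file.path(out_dir, "cox_univariate.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(univariate = uni$selected,
                              multivariate = mult$selected,
                              combined = sel$tc_id),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = FALSE)
    files <- c(files, "cox_univariate.tsv", "selection.json")
    counts$n_selected <- nrow(sel)
    timings$survival <- tic() - t0
  }
  if (stage_on("forest")) {
    t0 <- tic()
    fc <- config$forest
    forest <- surv_forest(fit$mixing, sim$survival, n_trees = fc$n_trees,
                          tcs_per_tree = min(fc$tcs_per_tree,
                                             nrow(fit$mixing)),
                          min_node_size = fc$min_node_size,
                          min_node_events = fc$min_node_events,
                          split_alpha = fc$split_alpha,
                          seed = seed + 30L)
    P <- final_proximity(forest)
    sub <- select_max_subgroups(P, sim$survival, k_max = fc$k_max,
                                alpha = fc$alpha)
    write.table(data.frame(sample_id = rownames(P), P, check.names = FALSE),
                file.path(out_dir, "proximity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(tc_id = names(forest$importance),
                           importance = forest$importance),
                file.path(out_dir, "importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = names(sub$labels),
                           subgroup = sub$labels),
                file.path(out_dir, "subgroups.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    files <- c(files, "proximity.tsv", "importance.tsv", "subgroups.csv")
    counts$n_subgroups <- sub$k
    timings$forest <- tic() - t0
  }
  if (stage_on("project")) {
    t0 <- tic()
    pc <- config$project
    A_self <- project(fit$components, sim$expression,
                      min_overlap = pc$min_overlap)
    write.table(data.frame(component_id = rownames(A_self), A_self,
                           check.names = FALSE),
                file.path(out_dir, "projected_activities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, "projected_activities.tsv")
    timings$project <- tic() - t0
  }
  manifest <- build_manifest(out_dir, files)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(counts = counts, manifest = manifest, params = config,
       timings_s = timings, out_dir = out_dir)
}

#' Split-dataset sensitivity analysis
#'
#' Decomposes the primary and secondary expression matrices independently,
#' matches the component sets (robust at |r| above the threshold), projects
#' the robust secondary components onto the survival (DFS) dataset, reruns
#' the permutation survival selection on both projections, builds the
#' forest twice (primary components vs robust secondary components) and
#' reports the Pearson correlation between the two final proximity
#' matrices. Secondary and DFS sample sets must be disjoint; overlapping
#' samples are an error.
#'
#' @param primary_X,secondary_X,dfs_X genes x samples expression matrices;
#'   `dfs_X` carries the survival-annotated samples.
#' @param surv survival data.frame for the `dfs_X` samples.
#' @param config configuration list (decompose / survival / forest /
#'   project blocks are honoured).
#' @return list with `matches`, `n_robust`, `selection_primary`,
#'   `selection_secondary`, `proximity_r`.
#' @export
run_sensitivity <- function(primary_X, secondary_X, dfs_X, surv,
                            config = default_config()) {
  if (length(intersect(colnames(secondary_X), colnames(dfs_X))) > 0)
    stop("secondary and DFS datasets share samples; they must be disjoint")
  dc <- config$decompose; sv <- config$survival
  fc <- config$forest; pc <- config$project
  seed <- config$seed
  fit1 <- cica(primary_X, n_runs = dc$n_runs,
               variance_threshold = dc$variance_threshold,
               r_threshold = dc$r_threshold,
               credibility_threshold = dc$credibility_threshold,
               seed = seed + 100L)
  fit2 <- cica(secondary_X, n_runs = dc$n_runs,
               variance_threshold = dc$variance_threshold,
               r_threshold = dc$r_threshold,
               credibility_threshold = dc$credibility_threshold,
               seed = seed + 200L)
  matches <- match_components(fit1$components, fit2$components,
                              r_threshold = pc$r_threshold)
  robust_sec <- matches$secondary[matches$robust]
  if (length(robust_sec) == 0)
    stop("no robust component matches between primary and secondary sets")
  W2 <- fit2$components$weights[robust_sec, , drop = FALSE]
  tc2 <- tcset(W2, credibility = fit2$components$credibility[robust_sec],
               standardize = FALSE)
  A1 <- project(fit1$components, dfs_X, min_overlap = pc$min_overlap)
  A2 <- project(tc2, dfs_X, min_overlap = pc$min_overlap)
  sel1 <- permutation_fdr_select(A1, surv, covariates = character(),
                                 n_perm = sv$n_perm, fdr = sv$fdr,
                                 confidence = sv$confidence,
                                 seed = seed + 300L)
  sel2 <- permutation_fdr_select(A2, surv, covariates = character(),
                                 n_perm = sv$n_perm, fdr = sv$fdr,
                                 confidence = sv$confidence,
                                 seed = seed + 301L)
  f1 <- surv_forest(A1, surv, n_trees = fc$n_trees,
                    tcs_per_tree = min(fc$tcs_per_tree, nrow(A1)),
                    min_node_size = fc$min_node_size,
                    min_node_events = fc$min_node_events,
                    split_alpha = fc$split_alpha, seed = seed + 400L)
  f2 <- surv_forest(A2, surv, n_trees = fc$n_trees,
                    tcs_per_tree = min(fc$tcs_per_tree, nrow(A2)),
                    min_node_size = fc$min_node_size,
                    min_node_events = fc$min_node_events,
                    split_alpha = fc$split_alpha, seed = seed + 401L)
  list(matches = matches,
       n_robust = sum(matches$robust),
       selection_primary = sel1,
       selection_secondary = sel2,
       proximity_r = compare_proximity(final_proximity(f1),
                                       final_proximity(f2)))
}
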