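# Random survival forest on component activities: log-rank-split survival
# trees over per-tree random feature subsets, summed co-terminal-node
# proximity, Ward-D2 patient stratification and candidacy-normalised
# importance scores.

#' Best log-rank split of a node on one activity vector
#'
#' Evaluates the two-sample log-rank statistic at every midpoint between
#' consecutive distinct values and returns the admissible cutpoint (children
#' respecting the size and event minima) with the maximal statistic.
#'
#' A split is admitted only when its maximized statistic is significant at
#' `split_alpha` after Bonferroni correction over the number of cutpoints
#' evaluated, so nodes whose candidates carry no survival signal stay
#' terminal; set `split_alpha = 1` to disable the significance gate.
#'
#' @param values numeric per-sample activity values.
#' @param surv survival data.frame aligned to `values`.
#' @param min_node_size minimum child size.
#' @param min_node_events minimum child event count.
#' @param split_alpha significance level for admitting a split (default
#'   0.05, Bonferroni-corrected over evaluated cutpoints).
#' @return list(cutpoint, statistic, p_adjusted) or `NULL` when no
#'   admissible split exists (including the all-values-identical and
#'   too-small-node cases).
#' @export
logrank_split <- function(values, surv, min_node_size = 15,
                          min_node_events = 5, split_alpha = 0.05) {
  validate_survival(surv)
  if (length(values) != nrow(surv)) stop("values and survival lengths differ")
  res <- .logrank_split_cpp(as.numeric(values), as.numeric(surv$time),
                            as.integer(surv$event), as.integer(min_node_size),
                            as.integer(min_node_events), split_alpha)
  if (!res$found) return(NULL)
  list(cutpoint = res$cutpoint, statistic = res$statistic,
       p_adjusted = res$p_adjusted)
}

#' Grow a single survival tree on a candidate component subset
#'
#' Recursive partitioning: at each node the best admissible (component,
#' cutpoint) pair over the candidates is chosen by maximal log-rank
#' statistic; recursion stops when no admissible split remains.
#'
#' @param activities components x samples mixing matrix.
#' @param surv survival data.frame aligned to the samples.
#' @param candidate_tcs component ids eligible for splitting in this tree.
#' @param min_node_size,min_node_events stopping minima.
#' @param split_alpha significance gate for splits (see [logrank_split]).
#' @param seed optional seed (the tree itself is deterministic; the seed is
#'   kept for provenance).
#' @return object of class `"tc_tree"`: node table (split_tc, cutpoint,
#'   statistic, left, right) plus `terminal`, the terminal-node id of every
#'   sample.
#' @export
grow_tree <- function(activities, surv, candidate_tcs, min_node_size = 15,
                      min_node_events = 5, split_alpha = 0.05, seed = NULL) {
  surv <- align_survival(activities, surv)
  ci <- match(candidate_tcs, rownames(activities))
  if (anyNA(ci)) stop("candidate components absent from activities")
  if (!is.null(seed)) set.seed(seed)
  res <- .grow_tree_cpp(activities, as.numeric(surv$time),
                        as.integer(surv$event), as.integer(ci - 1L),
                        as.integer(min_node_size), as.integer(min_node_events),
                        split_alpha)
  nodes <- data.frame(
    split_tc = ifelse(is.na(res$split_var), NA_character_,
                      rownames(activities)[res$split_var]),
    cutpoint = res$cutpoint, statistic = res$statistic,
    left = res$left, right = res$right, stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 terminal = setNames(res$terminal, colnames(activities)),
                 candidates = candidate_tcs, seed = seed),
            class = "tc_tree")
}

#' @method print tc_tree
#' @export
print.tc_tree <- function(x, ...) {
  n_split <- sum(!is.na(x$nodes$split_tc))
  cat(sprintf("Survival tree: %d splits, %d terminal nodes, candidates: %s\n",
              n_split, length(unique(x$terminal)),
              paste(x$candidates, collapse = ", ")))
  invisible(x)
}

#' Build a random survival forest on component activities
#'
#' Grows `n_trees` survival trees. Each tree draws a fresh uniform sample of
#' `tcs_per_tree` components (without replacement) as its candidate set and
#' sees all samples (no bootstrap), so the proximity diagonal equals
#' `n_trees` exactly. Per-tree proximity is the co-terminal-node indicator
#' over all sample pairs; the forest keeps the element-wise sum.
#'
#' @param activities components x samples mixing matrix.
#' @param surv survival data.frame aligned to the samples.
#' @param n_trees number of trees (default 1000).
#' @param tcs_per_tree candidate components per tree (default 5).
#' @param min_node_size,min_node_events stopping minima.
#' @param split_alpha significance gate for splits (see [logrank_split]).
#' @param seed integer seed.
#' @return object of class `"tc_rsf"` with `proximity` (summed counts),
#'   `used` and `candidate` (components x trees indicators), `importance`,
#'   `n_trees`, `params`.
#' @export
surv_forest <- function(activities, surv, n_trees = 1000, tcs_per_tree = 5,
                        min_node_size = 15, min_node_events = 5,
                        split_alpha = 0.05, seed = 1) {
  surv <- align_survival(activities, surv)
  k <- nrow(activities)
  if (k < tcs_per_tree)
    stop("fewer components than tcs_per_tree")
  set.seed(seed)
  res <- .grow_forest_cpp(activities, as.numeric(surv$time),
                          as.integer(surv$event), as.integer(n_trees),
                          as.integer(tcs_per_tree), as.integer(min_node_size),
                          as.integer(min_node_events), split_alpha)
  dimnames(res$proximity) <- list(colnames(activities), colnames(activities))
  dimnames(res$used) <- dimnames(res$candidate) <-
    list(rownames(activities), NULL)
  out <- structure(list(proximity = res$proximity, used = res$used,
                        candidate = res$candidate, n_trees = n_trees,
                        sample_ids = colnames(activities),
                        params = list(tcs_per_tree = tcs_per_tree,
                                      min_node_size = min_node_size,
                                      min_node_events = min_node_events,
                                      split_alpha = split_alpha,
                                      seed = seed)),
                   class = "tc_rsf")
  out$importance <- importance_scores(out)
  out
}

#' @rdname surv_forest
#' @export
build_forest <- surv_forest

#' @method print tc_rsf
#' @export
print.tc_rsf <- function(x, ...) {
  cat(sprintf("Random survival forest: %d trees, %d candidates/tree, %d samples\n",
              x$n_trees, x$params$tcs_per_tree, length(x$sample_ids)))
  top <- sort(x$importance, decreasing = TRUE)
  cat("top importance scores:\n")
  print(round(head(top, 5), 3))
  invisible(x)
}

#' @export
plot.tc_rsf <- function(x, ...) {
  graphics::barplot(sort(x$importance, decreasing = TRUE), las = 2,
                    ylab = "importance score", ylim = c(0, 1), ...)
  invisible(x)
}

#' Final summed proximity matrix of a forest
#'
#' Element-wise sum of the per-tree co-terminal-node indicator matrices; the
#' diagonal equals the number of trees exactly.
#'
#' @param forest a `"tc_rsf"` object.
#' @return symmetric samples x samples count matrix.
#' @export
final_proximity <- function(forest) {
  stopifnot(inherits(forest, "tc_rsf"))
  forest$proximity
}

#' Candidacy-normalised component importance scores
#'
#' For each component: the number of trees where it is used in at least one
#' split, divided by the number of trees where it was among the candidates
#' (0 when it was never a candidate). Bounded in \[0, 1\].
#'
#' @param forest a `"tc_rsf"` object.
#' @return named numeric vector.
#' @export
importance_scores <- function(forest) {
  stopifnot(inherits(forest, "tc_rsf"))
  n_used <- rowSums(forest$used)
  n_cand <- rowSums(forest$candidate)
  ifelse(n_cand == 0, 0, n_used / pmax(n_cand, 1))
}

#' Cluster patients on the forest proximity matrix
#'
#' Ward-D2 agglomerative clustering on the dissimilarity
#' `1 - proximity / n_trees`.
#'
#' @param P summed proximity matrix.
#' @param k number of subgroups (>= 2, <= samples).
#' @param n_trees number of trees used to build `P` (defaults to its
#'   diagonal).
#' @return named integer subgroup labels 1..k.
#' @export
cluster_proximity <- function(P, k, n_trees = P[1, 1]) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(P)) stop("k exceeds the number of samples")
  d <- as.dist(1 - P / n_trees)
  hc <- hclust(d, method = "ward.D2")
  cutree(hc, k = k)
}

#' Largest subgroup count with a significant log-rank difference
#'
#' For k = 2..k_max, clusters the proximity matrix and tests the k-sample
#' log-rank difference of the survival curves; returns the largest
#' significant k with its labels, or k = 1 (all samples in one group) when
#' no split is significant.
#'
#' @param P summed proximity matrix.
#' @param surv survival data.frame covering the samples of `P`.
#' @param k_max maximum subgroup count tried (default 10).
#' @param alpha log-rank significance level (default 0.05).
#' @param n_trees trees behind `P` (defaults to its diagonal).
#' @return list(k, labels, p_values) where p_values is the per-k log-rank
#'   p-value table.
#' @export
select_max_subgroups <- function(P, surv, k_max = 10, alpha = 0.05,
                                 n_trees = P[1, 1]) {
  surv <- surv[match(rownames(P), surv$sample_id), ]
  validate_survival(surv)
  k_max <- min(k_max, nrow(P) - 1)
  pvals <- rep(NA_real_, k_max)
  labs <- vector("list", k_max)
  for (k in 2:k_max) {
    lab <- cluster_proximity(P, k, n_trees)
    labs[[k]] <- lab
    if (length(unique(lab)) < 2 || min(table(lab)) < 1) next
    sd_ <- try(survdiff(Surv(surv$time, surv$event) ~ factor(lab)),
               silent = TRUE)
    if (inherits(sd_, "try-error")) next
    pvals[k] <- stats::pchisq(sd_$chisq, df = length(unique(lab)) - 1,
                              lower.tail = FALSE)
  }
  sig <- which(!is.na(pvals) & pvals < alpha)
  if (length(sig) == 0)
    return(list(k = 1L,
                labels = setNames(rep(1L, nrow(P)), rownames(P)),
                p_values = pvals))
  k_star <- max(sig)
  list(k = as.integer(k_star), labels = labs[[k_star]], p_values = pvals)
}

#' Pearson correlation between two proximity matrices
#'
#' Computed over the upper-triangle off-diagonal entries after aligning the
#' sample order.
#'
#' @param P1,P2 proximity matrices over the same samples.
#' @return Pearson r.
#' @export
compare_proximity <- function(P1, P2) {
  if (!setequal(rownames(P1), rownames(P2)))
    stop("proximity matrices cover different sample sets")
  P2 <- P2[rownames(P1), rownames(P1)]
  ut <- upper.tri(P1)
  cor(P1[ut], P2[ut])
}
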