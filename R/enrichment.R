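# Gene-set annotation of transcriptional components: Welch t enrichment of
# in-set vs out-of-set gene weights, Z transform, Bonferroni flagging,
# important-gene extraction and Spearman correlation of activities with
# continuous covariates.

#' Filter a gene set collection against a gene universe
#'
#' Deduplicates each set, intersects it with the universe, and drops sets
#' whose post-intersection size falls outside `[min_size, max_size]`.
#'
#' @param collection a [gene_sets] collection.
#' @param universe character vector of profiled genes.
#' @param min_size,max_size retained size range (default 10-500).
#' @return the filtered [gene_sets] collection (possibly empty, with a
#'   warning).
#' @export
filter_gene_sets <- function(collection, universe, min_size = 10,
                             max_size = 500) {
  if (length(universe) == 0) stop("gene universe is empty")
  filtered <- lapply(collection, function(g) intersect(unique(g), universe))
  sizes <- lengths(filtered)
  keep <- sizes >= min_size & sizes <= max_size
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("filter_gene_sets: dropped %d of %d sets outside [%d, %d]",
                    dropped, length(collection), min_size, max_size))
  out <- gene_sets(filtered[keep], name = attr(collection, "collection"))
  if (length(out) == 0) warning("no gene sets survive filtering")
  out
}

# Welch t statistic, Welch-Satterthwaite df, two-sided p and signed-normal
# Z for mean(in-set weights) vs mean(out-of-set weights); numerically stable
# for extreme t via log-space p-values.
welch_stats <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  if (any(se2 <= 0)) stop("zero variance in both groups; Welch t undefined")
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  log_p_half <- pt(-abs(t), df, log.p = TRUE)
  p <- pmin(2 * exp(log_p_half), 1)
  z <- -sign(t) * qnorm(log_p_half, log.p = TRUE)
  z[t == 0] <- 0
  list(t = t, df = df, p = p, z = z)
}

#' Welch t enrichment of a gene set in one component's weights
#'
#' Compares the weights of genes inside the set against all remaining
#' profiled genes with a two-sample Welch t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom); the two-sided p-value is
#' transformed into a signed standard-normal Z-score so sets of different
#' sizes are comparable.
#'
#' @param tc_weights named numeric vector of one component's gene weights.
#' @param gene_set character vector of gene identifiers.
#' @return list with `t`, `df`, `z`, `p`, `n_in`, `n_out`.
#' @export
welch_enrichment <- function(tc_weights, gene_set) {
  inset <- names(tc_weights) %in% gene_set
  n1 <- sum(inset); n2 <- sum(!inset)
  if (n1 < 2 || n2 < 2) stop("need >= 2 genes inside and outside the set")
  w1 <- tc_weights[inset]; w2 <- tc_weights[!inset]
  st <- welch_stats(mean(w1), stats::var(w1), n1, mean(w2), stats::var(w2), n2)
  c(st[c("t", "df", "z", "p")], list(n_in = n1, n_out = n2))
}

#' Score every (component, gene set) pair with Bonferroni flags
#'
#' Bonferroni correction is applied over the full table (components x sets).
#'
#' @param tcs a [tcset].
#' @param collection a filtered [gene_sets] collection.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns tc_id, set_id, welch_t, df, z_score,
#'   p_value, bonferroni_significant, n_in_set, n_out_set, sorted within
#'   component by descending |z|.
#' @export
enrichment_table <- function(tcs, collection, alpha = 0.05) {
  W <- tcs$weights
  if (length(collection) == 0)
    return(data.frame(tc_id = character(), set_id = character(),
                      welch_t = numeric(), df = numeric(),
                      z_score = numeric(), p_value = numeric(),
                      bonferroni_significant = logical(),
                      n_in_set = integer(), n_out_set = integer()))
  genes <- colnames(W)
  p_tot <- ncol(W)
  # per-component sufficient statistics over all genes
  tot_sum <- rowSums(W); tot_sq <- rowSums(W^2)
  rows <- vector("list", length(collection))
  member <- lapply(collection, function(g) genes %in% g)
  for (s in seq_along(collection)) {
    inset <- member[[s]]
    n1 <- sum(inset); n2 <- p_tot - n1
    s1 <- rowSums(W[, inset, drop = FALSE]); q1 <- rowSums(W[, inset, drop = FALSE]^2)
    m1 <- s1 / n1; v1 <- (q1 - n1 * m1^2) / (n1 - 1)
    m2 <- (tot_sum - s1) / n2; v2 <- (tot_sq - q1 - n2 * m2^2) / (n2 - 1)
    st <- welch_stats(m1, pmax(v1, 0), n1, m2, pmax(v2, 0), n2)
    rows[[s]] <- data.frame(tc_id = rownames(W), set_id = names(collection)[s],
                            welch_t = st$t, df = st$df, z_score = st$z,
                            p_value = st$p, n_in_set = n1, n_out_set = n2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  out$bonferroni_significant <- out$p_value <= alpha / n_tests
  out <- out[order(out$tc_id, -abs(out$z_score)), ]
  rownames(out) <- NULL
  out[, c("tc_id", "set_id", "welch_t", "df", "z_score", "p_value",
          "bonferroni_significant", "n_in_set", "n_out_set")]
}

#' Important genes of a component
#'
#' Genes whose standardized absolute weight reaches the threshold
#' (conventionally 3, i.e. three SDs), sorted by descending |weight|.
#'
#' @param tcs a [tcset].
#' @param component component id or index.
#' @param threshold absolute-weight cut (default 3).
#' @return named numeric vector of weights (possibly empty).
#' @export
important_genes <- function(tcs, component, threshold = 3.0) {
  w <- tcs$weights[component, ]
  sel <- w[abs(w) >= threshold]
  sel[order(-abs(sel))]
}

#' Spearman correlation of component activities with a continuous covariate
#'
#' Missing covariate values are dropped pairwise; requires at least three
#' complete pairs.
#'
#' @param mixing components x samples mixing matrix.
#' @param covariate numeric per-sample vector (may contain NA).
#' @return data.frame with tc_id, rho, p_value.
#' @export
activity_covariate_correlation <- function(mixing, covariate) {
  if (length(covariate) != ncol(mixing))
    stop("covariate must have one value per sample")
  ok <- !is.na(covariate)
  if (sum(ok) < 3) stop("need at least 3 non-missing paired samples")
  if (stats::var(covariate[ok]) == 0) stop("covariate is constant")
  res <- t(apply(mixing[, ok, drop = FALSE], 1, function(a) {
    ct <- cor.test(a, covariate[ok], method = "spearman", exact = FALSE)
    c(rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  data.frame(tc_id = rownames(mixing), rho = res[, "rho"],
             p_value = res[, "p_value"], row.names = NULL)
}
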