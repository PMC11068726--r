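# Cross-dataset projection of transcriptional components onto independent
# bulk, spatial or single-cell expression profiles, robustness matching of
# component sets, and permutation significance of per-unit activities.

#' Project components onto new expression data
#'
#' Intersects the component genes with the new matrix, re-standardizes the
#' weights on the intersection, gene-centers the new data (when more than
#' one sample is present) and solves the per-sample least-squares activity
#' coefficients.
#'
#' For unit-level significance maps (spatial spots, single cells) the
#' projection is taken uncentered (`center = FALSE`): each unit's activity
#' then measures the alignment of that unit's own expression with the
#' component weights, which is what the gene-label permutation null is
#' exchangeable against. Because the weights have mean zero, any baseline
#' shared across units only adds a constant per-component offset.
#'
#' @param tcs a [tcset].
#' @param X_new genes x samples expression matrix.
#' @param min_overlap minimum fraction of component genes that must be
#'   present in `X_new` (default 0.5).
#' @param center gene-center `X_new` across samples before the fit
#'   (default `TRUE`; ignored for single-sample input).
#' @return components x samples activity matrix; the achieved gene overlap
#'   fraction is attached as attribute `"overlap"`.
#' @export
project <- function(tcs, X_new, min_overlap = 0.5, center = TRUE) {
  genes <- intersect(tc_genes(tcs), rownames(X_new))
  overlap <- length(genes) / ncol(tcs$weights)
  if (overlap < min_overlap)
    stop(sprintf("gene overlap %.1f%% below the %.1f%% minimum (%d of %d genes)",
                 100 * overlap, 100 * min_overlap, length(genes),
                 ncol(tcs$weights)))
  S <- standardize_rows(tcs$weights[, genes, drop = FALSE])
  Xc <- X_new[genes, , drop = FALSE]
  if (!is.matrix(Xc)) Xc <- matrix(Xc, ncol = 1,
                                   dimnames = list(genes, colnames(X_new)))
  if (center && ncol(Xc) > 1) Xc <- Xc - rowMeans(Xc)
  A <- solve(S %*% t(S), S %*% Xc)
  dimnames(A) <- list(rownames(S), colnames(X_new))
  attr(A, "overlap") <- overlap
  A
}

#' Match two component sets by gene-weight correlation
#'
#' Greedy one-to-one matching in descending |Pearson r| between the gene
#' weights of the primary and secondary sets on their shared gene universe.
#' Matches with |r| above the threshold are flagged robust.
#'
#' @param primary,secondary [tcset] objects.
#' @param r_threshold robustness threshold on |r| (default 0.5).
#' @return data.frame (primary, secondary, r, robust) with unmatched
#'   component ids in attributes `"unmatched_primary"` /
#'   `"unmatched_secondary"`.
#' @export
match_components <- function(primary, secondary, r_threshold = 0.5) {
  genes <- intersect(tc_genes(primary), tc_genes(secondary))
  if (length(genes) < 3) stop("no shared gene universe")
  R <- cor(t(primary$weights[, genes, drop = FALSE]),
           t(secondary$weights[, genes, drop = FALSE]))
  k1 <- nrow(R); k2 <- ncol(R)
  ord <- order(-abs(R))
  used1 <- logical(k1); used2 <- logical(k2)
  out <- list()
  for (e in ord) {
    i <- (e - 1) %% k1 + 1; j <- (e - 1) %/% k1 + 1
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      primary = rownames(R)[i], secondary = colnames(R)[j],
      r = R[i, j], robust = abs(R[i, j]) > r_threshold,
      stringsAsFactors = FALSE)
    if (all(used1) || all(used2)) break
  }
  res <- do.call(rbind, out)
  res <- res[order(-abs(res$r)), ]
  rownames(res) <- NULL
  attr(res, "unmatched_primary") <- rownames(R)[!used1]
  attr(res, "unmatched_secondary") <- colnames(R)[!used2]
  res
}

#' Permutation significance of projected activities per unit
#'
#' Projects the components onto a profile (spatial spots or any unit-indexed
#' expression matrix) and builds a per-unit null by permuting the gene
#' labels of the component weight vectors `n_perm` times, recomputing all
#' activities each time. Two-sided empirical p-values use the add-one
#' correction, so the smallest achievable p is `1 / (n_perm + 1)`.
#'
#' @param tcs a [tcset].
#' @param profile genes x units expression matrix; a `"coordinates"`
#'   attribute (spot_id, row, col), when present, is carried into the output.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param min_overlap passed to [project()].
#' @return long data.frame: unit_id (plus coordinates if available), tc_id,
#'   activity, p_value, neg_log10_p.
#' @export
permutation_activity_significance <- function(tcs, profile, n_perm = 5000,
                                              seed = 1, min_overlap = 0.5) {
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  A_obs <- project(tcs, profile, min_overlap, center = FALSE)
  genes <- intersect(tc_genes(tcs), rownames(profile))
  S <- standardize_rows(tcs$weights[, genes, drop = FALSE])
  Xc <- profile[genes, , drop = FALSE]
  M <- solve(S %*% t(S))
  set.seed(seed)
  exceed <- matrix(0L, nrow(A_obs), ncol(A_obs))
  for (b in seq_len(n_perm)) {
    pr <- sample.int(length(genes))
    # permuting the gene labels of S equals permuting the rows of Xc;
    # the Gram matrix of S is invariant under the permutation
    Ab <- M %*% (S %*% Xc[pr, , drop = FALSE])
    exceed <- exceed + (abs(Ab) >= abs(A_obs))
  }
  p <- (exceed + 1) / (n_perm + 1)
  coords <- attr(profile, "coordinates")
  out <- data.frame(unit_id = rep(colnames(A_obs), each = nrow(A_obs)),
                    tc_id = rep(rownames(A_obs), ncol(A_obs)),
                    activity = as.numeric(A_obs),
                    p_value = as.numeric(p),
                    stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p_value)
  if (!is.null(coords))
    out <- merge(out, coords, by.x = "unit_id", by.y = "spot_id", sort = FALSE)
  out
}

# ---- Johnson SU normalisation -----------------------------------------------

#' Fit a Johnson-family normalising transformation by quantile matching
#'
#' Slifker-Shapiro fit from four symmetric quantiles (at +-z0 and +-3 z0 on
#' the normal scale). The quantile-ratio criterion mn/p^2 selects the
#' unbounded (SU, > 1) or bounded (SB, < 1) family; near-lognormal or
#' degenerate geometries fall back to a plain z-score. Returns a monotone
#' function mapping data to an approximately standard-normal scale.
#'
#' @param x numeric sample (the null distribution to normalise).
#' @param z0 base quantile on the normal scale (default 0.524).
#' @return function(y) giving normalised values; the fitted parameters are
#'   attached as attribute `"params"`.
#' @export
fit_johnson_su <- function(x, z0 = 0.524) {
  qs <- quantile(x, pnorm(c(-3, -1, 1, 3) * z0), names = FALSE, type = 8)
  x3m <- qs[1]; x1m <- qs[2]; x1 <- qs[3]; x3 <- qs[4]
  m <- x3 - x1; n_ <- x1m - x3m; p <- x1 - x1m
  fallback <- function() {
    mu <- mean(x); s <- sd(x)
    f <- function(y) (y - mu) / s
    attr(f, "params") <- list(family = "z", mean = mu, sd = s)
    f
  }
  if (p <= 0 || m <= 0 || n_ <= 0) return(fallback())
  ratio <- m * n_ / p^2
  tol <- 0.05                                 # near-lognormal band -> z-score
  if (ratio > 1 + tol) {                      # unbounded: Johnson SU
    mp <- m / p; np <- n_ / p
    delta <- 2 * z0 / acosh(0.5 * (mp + np))
    gamma <- delta * asinh((np - mp) / (2 * sqrt(ratio - 1)))
    lambda <- 2 * p * sqrt(ratio - 1) / ((mp + np - 2) * sqrt(mp + np + 2))
    xi <- (x1 + x1m) / 2 + p * (np - mp) / (2 * (mp + np - 2))
    f <- function(y) gamma + delta * asinh((y - xi) / lambda)
    attr(f, "params") <- list(family = "SU", gamma = gamma, delta = delta,
                              lambda = lambda, xi = xi)
    return(f)
  }
  if (ratio < 1 - tol) {                      # bounded: Johnson SB
    pm <- p / m; pn <- p / n_
    arg <- 0.5 * sqrt((1 + pm) * (1 + pn))
    if (arg <= 1) return(fallback())
    delta <- z0 / acosh(arg)
    gamma <- delta * asinh((pn - pm) *
                             sqrt((1 + pm) * (1 + pn) - 4) /
                             (2 * (1 / ratio - 1)))
    lambda <- p * sqrt(((1 + pm) * (1 + pn) - 2)^2 - 4) / (1 / ratio - 1)
    xi <- 0.5 * (x1 + x1m) - lambda / 2 +
      p * (pn - pm) / (2 * (1 / ratio - 1))
    f <- function(y) {
      eps <- 1e-10 * lambda
      y <- pmin(pmax(y, xi + eps), xi + lambda - eps)
      gamma + delta * log((y - xi) / (xi + lambda - y))
    }
    attr(f, "params") <- list(family = "SB", gamma = gamma, delta = delta,
                              lambda = lambda, xi = xi)
    return(f)
  }
  fallback()
}

#' Project components onto single-cell profiles with permutation significance
#'
#' Randomly subsamples the cells, projects the components, and builds a
#' gene-label permutation null as in
#' [permutation_activity_significance]. Activities are normalised by a
#' Johnson SU transformation fitted per component to its pooled null before
#' p-value computation, and per-cell-type distribution summaries (median and
#' quartiles) are reported for box-plot rendering.
#'
#' @param tcs a [tcset].
#' @param sc_matrix genes x cells expression matrix.
#' @param cell_labels per-cell type labels (named by cell or in column
#'   order).
#' @param n_perm permutations (default 3000).
#' @param subsample_fraction fraction of cells analysed (default 0.1).
#' @param seed integer seed.
#' @param min_overlap passed to [project()].
#' @return list with `cells` (cell_id, label, tc_id, activity, normalized,
#'   p_value) and `by_label` (label, tc_id, n, median, q25, q75 of
#'   normalised activity).
#' @export
single_cell_activity <- function(tcs, sc_matrix, cell_labels, n_perm = 3000,
                                 subsample_fraction = 0.1, seed = 1,
                                 min_overlap = 0.5) {
  if (length(cell_labels) != ncol(sc_matrix))
    stop("cell_labels must cover all cells")
  set.seed(seed)
  n_cells <- ncol(sc_matrix)
  keep <- if (subsample_fraction >= 1) seq_len(n_cells) else
    sort(sample.int(n_cells, max(2, round(subsample_fraction * n_cells))))
  X <- sc_matrix[, keep, drop = FALSE]
  labels <- as.character(cell_labels)[keep]
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small) > 0) {
    warning("excluding cell types with < 3 cells: ",
            paste(small, collapse = ", "))
    ok <- !(labels %in% small)
    X <- X[, ok, drop = FALSE]; labels <- labels[ok]
  }
  A_obs <- project(tcs, X, min_overlap, center = FALSE)
  genes <- intersect(tc_genes(tcs), rownames(X))
  S <- standardize_rows(tcs$weights[, genes, drop = FALSE])
  Xc <- X[genes, , drop = FALSE]
  M <- solve(S %*% t(S))
  null_act <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    pr <- sample.int(length(genes))
    null_act[[b]] <- M %*% (S %*% Xc[pr, , drop = FALSE])
  }
  k <- nrow(A_obs)
  norm_obs <- A_obs
  p <- A_obs
  for (j in seq_len(k)) {
    pool <- unlist(lapply(null_act, function(m) m[j, ]))
    f <- fit_johnson_su(pool)
    norm_obs[j, ] <- f(A_obs[j, ])
    p[j, ] <- 2 * pnorm(-abs(norm_obs[j, ]))
  }
  cells <- data.frame(cell_id = rep(colnames(A_obs), each = k),
                      label = rep(labels, each = k),
                      tc_id = rep(rownames(A_obs), ncol(A_obs)),
                      activity = as.numeric(A_obs),
                      normalized = as.numeric(norm_obs),
                      p_value = as.numeric(p),
                      stringsAsFactors = FALSE)
  by_label <- do.call(rbind, lapply(split(cells, cells[c("label", "tc_id")]),
    function(d) data.frame(label = d$label[1], tc_id = d$tc_id[1],
                           n = nrow(d),
                           median = median(d$normalized),
                           q25 = quantile(d$normalized, 0.25, names = FALSE),
                           q75 = quantile(d$normalized, 0.75, names = FALSE),
                           stringsAsFactors = FALSE)))
  rownames(by_label) <- NULL
  list(cells = cells, by_label = by_label)
}
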