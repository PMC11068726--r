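# Consensus ICA: repeated randomly initialised ICA runs, cross-run clustering
# of components at |Pearson r| > 0.9, cluster-size capping, consensus
# averaging, credibility filtering, least-squares mixing-matrix estimation
# and reconstruction.

#' Cluster components across ICA runs
#'
#' Components from all runs whose pairwise absolute Pearson correlation
#' exceeds `r_threshold` are agglomerated greedily in descending |r| edge
#' order. A merge is refused when it would exceed `max_cluster_size`, when it
#' would place two components from the same run in one cluster, or when any
#' cross-pair correlation falls at or below the threshold (so every cluster
#' is fully mutually correlated). Members are sign-aligned to the cluster's
#' first component.
#'
#' @param runs list of single-ICA results (each with a `components` matrix).
#' @param r_threshold absolute correlation threshold.
#' @param max_cluster_size cap on cluster size; defaults to the number of
#'   runs, so no cluster can exceed the total number of ICA runs.
#' @return list of clusters, each with `members` (data.frame run, component,
#'   sign) and `consensus` (the sign-aligned mean weight vector).
#' @export
cluster_components <- function(runs, r_threshold = 0.9,
                               max_cluster_size = length(runs)) {
  if (length(runs) < 1) stop("need at least one ICA run")
  M <- do.call(rbind, lapply(runs, `[[`, "components"))
  run_of <- rep(seq_along(runs), vapply(runs, function(r) nrow(r$components), 1L))
  comp_of <- unlist(lapply(runs, function(r) seq_len(nrow(r$components))))
  m <- nrow(M)
  cl <- seq_len(m)                       # cluster id per component
  if (m > 1) {
    R <- cor(t(M))
    aR <- abs(R)
    idx <- which(upper.tri(aR) & aR > r_threshold, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      ord <- order(aR[idx], decreasing = TRUE)
      for (e in ord) {
        a <- idx[e, 1]; b <- idx[e, 2]
        ca <- cl[a]; cb <- cl[b]
        if (ca == cb) next
        mA <- which(cl == ca); mB <- which(cl == cb)
        if (length(mA) + length(mB) > max_cluster_size) next
        if (any(run_of[mA] %in% run_of[mB])) next
        if (min(aR[mA, mB]) <= r_threshold) next
        cl[mB] <- ca
      }
    }
  }
  lapply(unique(cl), function(id) {
    mem <- which(cl == id)
    ref <- mem[1]
    sgn <- if (length(mem) == 1) 1 else
      sign(sapply(mem, function(j) if (j == ref) 1 else cor(M[ref, ], M[j, ])))
    cons <- colMeans(M[mem, , drop = FALSE] * sgn)
    list(members = data.frame(run = run_of[mem], component = comp_of[mem],
                              sign = as.integer(sgn)),
         consensus = cons)
  })
}

#' Build consensus components from cross-run clusters
#'
#' The consensus weight vector of each cluster is the mean of its
#' sign-aligned members, re-standardized to mean 0, SD 1 across genes. The
#' credibility index is cluster size divided by the number of runs; only
#' components with credibility at or above the threshold are retained,
#' ordered by descending credibility (ties by first occurrence). Each
#' retained component is oriented so its gene-weight skewness is positive.
#'
#' @param clusters output of [cluster_components].
#' @param n_runs total number of ICA runs.
#' @param credibility_threshold minimum credibility to retain (default 0.5).
#' @param gene_ids gene names for the consensus weights.
#' @return a [tcset].
#' @export
build_consensus <- function(clusters, n_runs, credibility_threshold = 0.5,
                            gene_ids = NULL) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  cred <- vapply(clusters, function(cl) nrow(cl$members) / n_runs, 0)
  keep <- which(cred >= credibility_threshold - 1e-12)
  if (length(keep) == 0)
    stop("no component reaches the credibility threshold")
  keep <- keep[order(-cred[keep], keep)]
  W <- do.call(rbind, lapply(clusters[keep], `[[`, "consensus"))
  if (!is.null(gene_ids)) colnames(W) <- gene_ids
  if (is.null(colnames(W))) colnames(W) <- paste0("g", seq_len(ncol(W)))
  W <- standardize_rows(W)
  W <- canonicalize_signs(W)
  rownames(W) <- paste0("TC", seq_along(keep))
  tcset(W, credibility = cred[keep], standardize = FALSE)
}

# orient rows so gene-weight skewness is positive; on (near-)symmetric rows
# fall back to making the largest-|weight| gene positive
canonicalize_signs <- function(W) {
  for (k in seq_len(nrow(W))) {
    w <- W[k, ]
    sk <- mean((w - mean(w))^3) / (sd(w)^3 + 1e-300)
    s <- if (abs(sk) > 1e-8) sign(sk) else sign(w[which.max(abs(w))])
    if (s < 0) W[k, ] <- -w
  }
  W
}

#' Estimate the mixing matrix by least squares
#'
#' Finds per-sample activity coefficients such that the inner product of
#' activities and consensus weights best reconstructs each sample's
#' gene-centered expression.
#'
#' @param X genes x samples expression matrix.
#' @param tcs a [tcset]; its genes must all be present in `X`.
#' @return components x samples mixing matrix.
#' @export
estimate_mixing <- function(X, tcs) {
  validate_expression(X)
  genes <- intersect(tc_genes(tcs), rownames(X))
  if (length(genes) < ncol(tcs$weights))
    stop("expression matrix is missing genes present in the component set")
  S <- tcs$weights[, genes, drop = FALSE]
  Xc <- X[genes, , drop = FALSE]
  Xc <- Xc - rowMeans(Xc)
  G <- S %*% t(S)
  rk <- qr(t(S))$rank
  if (rk < nrow(S)) {
    q <- qr(t(S))
    bad <- rownames(S)[q$pivot[(rk + 1):nrow(S)]]
    stop("collinear components in weight matrix: ", paste(bad, collapse = ", "))
  }
  A <- solve(G, S %*% Xc)
  dimnames(A) <- list(rownames(S), colnames(X))
  A
}

#' Reconstruct expression from components and mixing coefficients
#'
#' @param tcs a [tcset].
#' @param mixing components x samples mixing matrix.
#' @param X optional original matrix; if given, per-sample and overall R^2
#'   against the gene-centered original are reported.
#' @return list with `values` (genes x samples, gene-centered scale),
#'   `r2_overall` and `r2_sample` (NULL without `X`).
#' @export
reconstruct <- function(tcs, mixing, X = NULL) {
  if (!identical(rownames(mixing), component_ids(tcs)))
    stop("component ids of mixing matrix and component set differ")
  R <- crossprod(tcs$weights, mixing)
  r2o <- r2s <- NULL
  if (!is.null(X)) {
    genes <- tc_genes(tcs)
    if (!all(genes %in% rownames(X))) stop("dimension mismatch with original matrix")
    Xc <- X[genes, colnames(mixing), drop = FALSE]
    Xc <- Xc - rowMeans(Xc)
    ss_tot <- sum(Xc^2)
    r2o <- 1 - sum((Xc - R)^2) / ss_tot
    r2s <- 1 - colSums((Xc - R)^2) / pmax(colSums(Xc^2), .Machine$double.eps)
  }
  list(values = R, r2_overall = r2o, r2_sample = r2s)
}

#' Consensus independent component analysis of an expression matrix
#'
#' The central fitting function. Selects the component count by the
#' cumulative explained-variance threshold on the between-sample covariance
#' PCA, performs `n_runs` randomly initialised ICA runs on the whitened data,
#' clusters components across runs at |r| > `r_threshold` (cluster size
#' capped at `n_runs`), averages clusters into consensus transcriptional
#' components, drops components with credibility below
#' `credibility_threshold`, and estimates the mixing matrix by least squares.
#' Within equal credibility, components are ordered by descending explained
#' activity variance. All run seeds derive deterministically from
#' `seed`.
#'
#' @param X genes x samples expression matrix (log-scale continuous).
#' @param n_runs number of ICA runs (default 25).
#' @param variance_threshold PCA explained-variance threshold (default 0.85).
#' @param r_threshold cross-run clustering correlation threshold (default 0.9).
#' @param credibility_threshold minimum credibility index (default 0.5).
#' @param seed master seed.
#' @param max_iter,tol fixed-point ICA controls.
#' @param on_nonconvergence passed to the ICA core; `"error"` (default) or
#'   `"warn"`.
#' @return an object of class `"cica"` with elements `components` (a
#'   [tcset]), `mixing`, `credibility`, `n_components`, `cluster_sizes`,
#'   `r2_overall`, `r2_sample`, `gene_means`, `seed`, `params`, `call`.
#' @seealso [predict.cica()] to project onto new data, [coef.cica()] for the
#'   mixing matrix.
#' @export
cica <- function(X, n_runs = 25, variance_threshold = 0.85, r_threshold = 0.9,
                 credibility_threshold = 0.5, seed = 1, max_iter = 1000,
                 tol = 1e-6, on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  validate_expression(X)
  if (n_runs < 1) stop("n_runs must be >= 1")
  i <- select_n_components(X, variance_threshold)
  wh <- whiten_expression(X, i)
  set.seed(seed)
  run_seeds <- sample.int(2147483646L, n_runs)
  runs <- lapply(run_seeds, function(s) {
    r <- fastica_run(wh$Z, s, max_iter, tol, on_nonconvergence)
    colnames(r$components) <- rownames(X)
    r
  })
  clusters <- if (n_runs == 1) {
    cluster_components(runs, r_threshold, max_cluster_size = 1)
  } else cluster_components(runs, r_threshold, max_cluster_size = n_runs)
  tcs <- build_consensus(clusters, n_runs, credibility_threshold,
                         gene_ids = rownames(X))
  A <- estimate_mixing(X, tcs)
  # within equal credibility, order by explained activity variance
  expl <- rowSums(A^2)
  ord <- order(-tcs$credibility, -expl)
  if (!identical(ord, seq_along(ord))) {
    W <- tcs$weights[ord, , drop = FALSE]
    cred <- tcs$credibility[ord]
    rownames(W) <- paste0("TC", seq_along(ord))
    tcs <- tcset(W, credibility = unname(cred), standardize = FALSE)
    A <- A[ord, , drop = FALSE]
    rownames(A) <- rownames(W)
  }
  rec <- reconstruct(tcs, A, X)
  structure(list(components = tcs, mixing = A,
                 credibility = tcs$credibility,
                 n_components = i,
                 cluster_sizes = vapply(clusters, function(cl) nrow(cl$members), 1L),
                 r2_overall = rec$r2_overall, r2_sample = rec$r2_sample,
                 gene_means = rowMeans(X), X = X,
                 seed = seed,
                 params = list(n_runs = n_runs,
                               variance_threshold = variance_threshold,
                               r_threshold = r_threshold,
                               credibility_threshold = credibility_threshold),
                 call = match.call()),
            class = "cica")
}

#' @method print cica
#' @export
print.cica <- function(x, ...) {
  cat("Consensus ICA decomposition\n")
  cat(sprintf("  %d samples, %d genes; %d PCA dimensions (>= %.0f%% variance)\n",
              ncol(x$X), nrow(x$X), x$n_components,
              100 * x$params$variance_threshold))
  cat(sprintf("  %d ICA runs -> %d consensus TCs (credibility >= %.2f)\n",
              x$params$n_runs, nrow(x$components$weights),
              x$params$credibility_threshold))
  cat(sprintf("  reconstruction R^2 = %.3f\n", x$r2_overall))
  invisible(x)
}

#' @method summary cica
#' @export
summary.cica <- function(object, ...) {
  out <- list(n_tc = nrow(object$components$weights),
              n_components = object$n_components,
              credibility = object$credibility,
              cluster_sizes = object$cluster_sizes,
              r2_overall = object$r2_overall,
              r2_sample = summary(object$r2_sample),
              params = object$params)
  class(out) <- "summary.cica"
  out
}

#' @method print summary.cica
#' @export
print.summary.cica <- function(x, ...) {
  cat(sprintf("Consensus ICA: %d TCs from %d PCA dimensions\n",
              x$n_tc, x$n_components))
  cat("credibility indices:\n"); print(round(x$credibility, 3))
  cat(sprintf("cluster sizes: %s\n",
              paste(sort(x$cluster_sizes, decreasing = TRUE), collapse = " ")))
  cat(sprintf("overall reconstruction R^2: %.4f\n", x$r2_overall))
  invisible(x)
}

#' Mixing matrix of a consensus ICA fit
#' @param object a `"cica"` fit.
#' @param ... unused.
#' @return components x samples activity matrix.
#' @export
coef.cica <- function(object, ...) object$mixing

#' Project a consensus ICA fit onto new expression data
#' @param object a `"cica"` fit.
#' @param newdata genes x samples expression matrix.
#' @param ... passed to [project()].
#' @return components x samples activity matrix on the new data.
#' @export
predict.cica <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$mixing)
  project(object$components, newdata, ...)
}

#' @export
fitted.cica <- function(object, ...) {
  reconstruct(object$components, object$mixing)$values + object$gene_means
}

#' @export
residuals.cica <- function(object, ...) object$X - fitted(object)

#' @export
plot.cica <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::barplot(x$credibility, las = 2, ylim = c(0, 1),
                    main = "Credibility index", ylab = "fraction of runs")
  graphics::abline(h = x$params$credibility_threshold, lty = 2)
  graphics::plot(sort(x$r2_sample), ylab = expression(R^2),
                 xlab = "sample (sorted)", main = "Per-sample reconstruction")
  invisible(x)
}
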