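# Single-run ICA machinery: component-count selection by explained variance,
# whitening via PCA on the between-sample covariance matrix, and a fixed-point
# ICA with the log-cosh negentropy contrast and symmetric decorrelation.
# Components live in gene space: the data model is X (genes x samples) =
# t(S) %*% A with statistically independent gene-weight sources in the rows
# of S.

#' Select the number of components by cumulative explained variance
#'
#' Performs PCA on the covariance matrix between samples (genes are
#' mean-centered across samples first) and returns the minimum number of top
#' principal components whose cumulative explained-variance fraction reaches
#' the threshold.
#'
#' @param X genes x samples expression matrix.
#' @param variance_threshold fraction of total variance to capture, in (0, 1].
#' @return integer component count.
#' @export
select_n_components <- function(X, variance_threshold = 0.85) {
  validate_expression(X)
  if (ncol(X) < 2) stop("need at least 2 samples")
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must lie in (0, 1]")
  ev <- sample_cov_eigen(X)$values
  total <- sum(ev)
  if (total <= .Machine$double.eps * length(ev))
    stop("expression matrix has zero total variance")
  cum <- cumsum(ev) / total
  as.integer(which(cum >= variance_threshold - 1e-12)[1])
}

# eigendecomposition of the between-sample covariance of gene-centered data
sample_cov_eigen <- function(X) {
  Xc <- X - rowMeans(X)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e$centered <- Xc
  e
}

# Whiten to i components. Returns Z (i x genes) with ZZ'/p = I, plus the
# centered data and eigeninfo needed downstream.
whiten_expression <- function(X, n_components) {
  p <- nrow(X)
  e <- sample_cov_eigen(X)
  if (n_components > sum(e$values > 1e-12 * max(e$values)))
    stop("requested more components than the numerical rank of the data")
  U <- e$vectors[, seq_len(n_components), drop = FALSE]
  lam <- e$values[seq_len(n_components)]
  Y <- e$centered %*% U                        # p x i, col j has SS lam_j*(p-1)
  Z <- t(Y) / sqrt(lam * (p - 1) / p)          # rows have mean-square 1
  list(Z = Z, eigenvalues = e$values, centered = e$centered)
}

# Symmetric fixed-point ICA (log-cosh contrast) on whitened rows Z (i x p).
# Returns the orthogonal unmixing matrix W (i x i).
fastica_core <- function(Z, seed, max_iter = 1000, tol = 1e-6) {
  i <- nrow(Z); p <- ncol(Z)
  set.seed(seed)
  W <- matrix(rnorm(i * i), i, i)
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- (G %*% t(Z)) / p - diag(rowMeans(1 - G^2), i) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, iterations = it)
}

# W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

#' Run a single randomly initialised ICA
#'
#' Whitens the gene-centered expression matrix to `n_components` dimensions
#' and runs fixed-point ICA (log-cosh negentropy, symmetric decorrelation)
#' from a random initial weight matrix of unit variance. Deterministic given
#' the seed. Each returned component has unit variance across genes.
#'
#' @param X genes x samples expression matrix.
#' @param n_components number of components to extract.
#' @param seed integer run seed.
#' @param max_iter,tol fixed-point iteration controls.
#' @param on_nonconvergence `"error"` (default) aborts naming the run seed;
#'   `"warn"` returns the last iterate with a warning (ICA is unidentifiable
#'   for Gaussian-only data, where the iteration may wander between
#'   equivalent rotations).
#' @return list with `seed`, `components` (n_components x genes) and
#'   `converged`.
#' @export
run_single_ica <- function(X, n_components, seed, max_iter = 1000, tol = 1e-6,
                           on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (n_components > min(dim(X)))
    stop("n_components exceeds min(genes, samples)")
  wh <- whiten_expression(X, n_components)
  res <- fastica_run(wh$Z, seed, max_iter, tol, on_nonconvergence)
  res$components <- structure(res$components,
                              dimnames = list(NULL, rownames(X)))
  res
}

# ICA on a prewhitened Z; shared by run_single_ica and the consensus driver
fastica_run <- function(Z, seed, max_iter = 1000, tol = 1e-6,
                        on_nonconvergence = "error") {
  fit <- fastica_core(Z, seed, max_iter, tol)
  if (!fit$converged) {
    msg <- sprintf("ICA run with seed %d did not converge in %d iterations",
                   seed, max_iter)
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  S <- fit$W %*% Z
  # unit variance across genes (rows of Z have mean-square 1, W orthogonal)
  S <- S / sqrt(rowSums((S - rowMeans(S))^2) / (ncol(S) - 1))
  list(seed = seed, components = S, converged = fit$converged)
}
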