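#' @useDynLib tcdissect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust as.dist qnorm pnorm pt rnorm rexp runif
#'   sd quantile median coef predict fitted residuals ks.test cor.test
#'   ecdf setNames
#' @importFrom utils write.table read.delim head
NULL

# ---- expression matrices -----------------------------------------------------

#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene identifiers
#' as row names and unique sample identifiers as column names, on a log-like
#' continuous scale, with no missing values.
#'
#' @param X numeric matrix, genes in rows, samples in columns.
#' @return `X`, invisibly, after validation.
#' @export
validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(X))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(X))) stop("duplicated sample identifiers")
  if (anyNA(X) || any(!is.finite(X))) stop("expression matrix contains missing or non-finite values")
  invisible(X)
}

# ---- transcriptional component sets -----------------------------------------

#' Construct a set of transcriptional components (TCs)
#'
#' A TC set stores a components-by-genes weight matrix together with a
#' per-component credibility index (the fraction of ICA runs that contributed
#' a member to the component's consensus cluster). Each component's weights
#' are standardized to mean 0, standard deviation 1 across genes, so that a
#' weight behaves like a z-score and the conventional "important gene" cut at
#' |weight| >= 3 has its usual interpretation.
#'
#' @param weights numeric matrix, components in rows (named), genes in columns
#'   (named).
#' @param credibility numeric vector in (0, 1], one value per component.
#' @param standardize logical; if `TRUE` (default) rows are re-standardized.
#' @return an object of class `"tcset"`.
#' @export
tcset <- function(weights, credibility = rep(1, nrow(weights)), standardize = TRUE) {
  if (!is.matrix(weights) || !is.numeric(weights)) stop("weights must be a numeric matrix")
  if (is.null(colnames(weights))) stop("weights need gene column names")
  if (is.null(rownames(weights)))
    rownames(weights) <- paste0("TC", seq_len(nrow(weights)))
  if (length(credibility) != nrow(weights))
    stop("credibility must have one value per component")
  if (any(credibility <= 0) || any(credibility > 1))
    stop("credibility indices must lie in (0, 1]")
  if (standardize) weights <- standardize_rows(weights)
  structure(list(weights = weights,
                 credibility = setNames(as.numeric(credibility), rownames(weights))),
            class = "tcset")
}

#' @method print tcset
#' @export
print.tcset <- function(x, ...) {
  cat(sprintf("Transcriptional component set: %d components x %d genes\n",
              nrow(x$weights), ncol(x$weights)))
  cat(sprintf("credibility: min %.2f, median %.2f, max %.2f\n",
              min(x$credibility), median(x$credibility), max(x$credibility)))
  invisible(x)
}

#' @export
dim.tcset <- function(x) dim(x$weights)

component_ids <- function(tcs) rownames(tcs$weights)
tc_genes <- function(tcs) colnames(tcs$weights)

# standardize rows of a matrix to mean 0, sd 1 (denominator n - 1)
standardize_rows <- function(M) {
  mu <- rowMeans(M)
  M <- M - mu
  s <- sqrt(rowSums(M^2) / (ncol(M) - 1))
  if (any(s == 0)) stop("cannot standardize a constant component")
  M / s
}

# ---- survival tables --------------------------------------------------------

#' Validate a per-sample survival table
#'
#' Columns `sample_id`, `time` (months, strictly positive) and `event`
#' (0 = censored, 1 = event) are required; any further columns are treated as
#' clinical covariates. Categorical covariates may carry an explicit
#' `"unknown"` level.
#'
#' @param surv a data.frame.
#' @return `surv`, invisibly.
#' @export
validate_survival <- function(surv) {
  if (!is.data.frame(surv)) stop("survival data must be a data.frame")
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(surv)))
    stop("survival table must have columns sample_id, time, event")
  if (any(surv$time <= 0)) stop("survival times must be strictly positive")
  if (!all(surv$event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (anyDuplicated(surv$sample_id)) stop("duplicated sample_id in survival table")
  invisible(surv)
}

# align a survival table to the columns of a mixing matrix
align_survival <- function(mixing, surv) {
  validate_survival(surv)
  ids <- colnames(mixing)
  if (!all(ids %in% surv$sample_id))
    stop("survival table is missing samples present in the mixing matrix")
  surv[match(ids, surv$sample_id), , drop = FALSE]
}

# ---- gene set collections ---------------------------------------------------

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param name collection name.
#' @return an object of class `"gene_sets"`.
#' @export
gene_sets <- function(sets, name = "collection") {
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("gene sets must have unique names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, class = "gene_sets", collection = name)
}

#' @method print gene_sets
#' @export
print.gene_sets <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Gene set collection '%s': %d sets (sizes %d-%d)\n",
              attr(x, "collection"), length(x), min(sizes), max(sizes)))
  invisible(x)
}
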