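# Plain-text readers and writers for the pipeline's standard formats:
# TSV expression and component matrices, CSV survival tables, GMT gene set
# collections and MTX spatial profiles with spot coordinates.

#' Write / read a genes-by-samples expression matrix as TSV
#'
#' Genes in rows, a leading `gene_id` column, sample ids in the header.
#'
#' @param X genes x samples matrix.
#' @param path file path.
#' @return `read_expression_tsv` returns the matrix.
#' @export
write_expression_tsv <- function(X, path) {
  validate_expression(X)
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  storage.mode(X) <- "double"
  validate_expression(X)
  X
}

#' Write / read a survival table as CSV
#' @param surv survival data.frame.
#' @param path file path.
#' @export
write_survival_csv <- function(surv, path) {
  validate_survival(surv)
  write.table(surv, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  surv <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survival(surv)
  surv
}

#' Write / read gene set collections in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param collection a [gene_sets] collection.
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, attr(collection, "collection"), collection[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  dups <- sum(lengths(lapply(parts, function(p) p[-(1:2)])) - lengths(sets))
  if (dups > 0)
    message(sprintf("read_gmt: removed %d duplicate gene entries", dups))
  gene_sets(sets, name = parts[[1]][2])
}

#' Write a component set as TSV plus a JSON sidecar
#'
#' The TSV holds components in rows and genes in columns; the sidecar
#' records credibility indices and any parameters supplied.
#'
#' @param tcs a [tcset].
#' @param path TSV path; the sidecar is written at `<path>.json`.
#' @param params optional named list stored in the sidecar.
#' @export
write_tcset <- function(tcs, path, params = list()) {
  df <- data.frame(component_id = rownames(tcs$weights), tcs$weights,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(credibility = as.list(tcs$credibility),
                            params = params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tcset
#' @export
read_tcset <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  storage.mode(W) <- "double"
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tcset(W, credibility = unlist(meta$credibility), standardize = FALSE)
}

#' Write / read a spatial profile as MTX plus coordinate and feature files
#'
#' `<prefix>.mtx` holds the sparse genes x spots matrix,
#' `<prefix>_genes.tsv` and `<prefix>_spots.tsv` the identifiers, and
#' `<prefix>_coords.csv` the spot coordinates (spot_id, row, col).
#'
#' @param X genes x spots matrix with a `"coordinates"` attribute.
#' @param prefix path prefix.
#' @export
write_spatial_mtx <- function(X, prefix) {
  coords <- attr(X, "coordinates")
  if (is.null(coords)) stop("spatial matrix lacks a coordinates attribute")
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(X), paste0(prefix, "_genes.tsv"))
  writeLines(colnames(X), paste0(prefix, "_spots.tsv"))
  write.table(coords, paste0(prefix, "_coords.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_spatial_mtx
#' @export
read_spatial_mtx <- function(prefix) {
  X <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(X) <- readLines(paste0(prefix, "_genes.tsv"))
  colnames(X) <- readLines(paste0(prefix, "_spots.tsv"))
  coords <- utils::read.csv(paste0(prefix, "_coords.csv"),
                            stringsAsFactors = FALSE)
  attr(X, "coordinates") <- coords
  X
}
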