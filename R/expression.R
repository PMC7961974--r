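#' Expression matrices and their processing stage
#'
#' The pipeline's payload is a plain numeric matrix with genes in rows and
#' samples in columns, carrying a `stage` attribute that records how far it
#' has been processed: `"raw"` (linear intensities), `"log2"`, `"normalized"`
#' (quantile normalized log2) or `"centralized"` (gene-wise mean removed,
#' values are differential expression in log2 units).
#'
#' @param x A numeric matrix with unique rownames (gene ids) and colnames
#'   (sample ids), or a data frame whose first column holds gene ids.
#' @param stage Processing stage tag of the values in `x`.
#' @return A numeric matrix with a `stage` attribute.
#' @export
#' @examples
#' m <- as_expression_matrix(matrix(2^rnorm(20, 7), 5, 4,
#'   dimnames = list(paste0("g", 1:5), paste0("s", 1:4))))
#' expression_stage(m)
as_expression_matrix <- function(x, stage = c("raw", "log2", "normalized",
                                              "centralized")) {
  stage <- match.arg(stage)
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[-1])
    rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expression values must be a numeric matrix or a data frame")
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    abort("gene ids (rownames) must be present and unique")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    abort("sample ids (colnames) must be present and unique")
  }
  structure(x, stage = stage)
}

#' @rdname as_expression_matrix
#' @param m An expression matrix.
#' @export
expression_stage <- function(m) attr(m, "stage") %||% "raw"

set_stage <- function(m, stage) {
  attr(m, "stage") <- stage
  m
}

require_stage <- function(m, allowed, op) {
  st <- expression_stage(m)
  if (!st %in% allowed) {
    abort(sprintf("%s expects a matrix at stage %s, got '%s'",
                  op, paste(sQuote(allowed), collapse = " or "), st))
  }
  invisible(st)
}

#' Log2-transform raw intensities
#'
#' Values are clamped at 1 before taking `log2()`, so non-positive raw
#' intensities map to 0 rather than `-Inf`.
#'
#' @param m Expression matrix at stage `"raw"`.
#' @return Expression matrix at stage `"log2"` with no non-finite values.
#' @export
log_transform <- function(m) {
  require_stage(m, "raw", "log_transform()")
  if (!is.numeric(m)) abort("non-numeric expression values")
  out <- log2(pmax(m, 1))
  if (any(!is.finite(out))) abort("non-finite values after log transform")
  set_stage(out, "log2")
}

#' Quantile-normalize log2 intensities
#'
#' Forces every sample to share the cross-sample mean empirical distribution
#' by rank alignment (via [limma::normalizeQuantiles()]); ties within a
#' sample receive the mean of the reference values at their tied ranks.
#' A single-sample matrix is returned unchanged with a warning.
#'
#' @param m Expression matrix at stage `"log2"`.
#' @return Expression matrix at stage `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  require_stage(m, "log2", "quantile_normalize()")
  if (ncol(m) < 2) {
    warn("quantile normalization needs >= 2 samples; returning input unchanged")
    return(set_stage(m, "normalized"))
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  set_stage(as.matrix(out), "normalized")
}

#' Centralize genes
#'
#' Subtracts each gene's mean across samples, turning the values into
#' differential expression (delta-e) in log2 units — the representation the
#' SOM is trained on.
#'
#' @param m Expression matrix at stage `"normalized"` (a `"log2"` matrix is
#'   accepted too, e.g. for noise-free constructions).
#' @return Expression matrix at stage `"centralized"`, all row means 0.
#' @export
centralize <- function(m) {
  require_stage(m, c("normalized", "log2", "centralized"), "centralize()")
  out <- m - rowMeans(m)
  set_stage(out, "centralized")
}

#' Read / write expression matrices as TSV
#'
#' The on-disk format is tab-separated with a `gene_id` first column and one
#' column per sample.
#'
#' @param path File path.
#' @param stage Stage tag to attach to the values read.
#' @return `read_expression_tsv()` returns an expression matrix;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, stage = "raw") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_expression_matrix(as.data.frame(df), stage = stage)
}

#' @rdname read_expression_tsv
#' @param m Expression matrix.
#' @export
write_expression_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
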