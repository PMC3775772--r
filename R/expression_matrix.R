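#' Construct a gene-by-sample expression matrix
#'
#' An `expr_matrix` is a plain numeric matrix of non-negative expression
#' values (RPKM) with unique gene ids as row names, unique sample ids as
#' column names, and a short dataset label carried as an attribute. All
#' downstream stability statistics operate on this container.
#'
#' @param values Numeric matrix, genes as rows, samples as columns. All
#'   entries must be finite and >= 0.
#' @param gene_ids Optional character vector of gene ids; defaults to
#'   `rownames(values)`.
#' @param sample_ids Optional character vector of sample ids; defaults to
#'   `colnames(values)`.
#' @param dataset_label Short text label naming the dataset (cohort).
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), dataset_label = "toy")
#' dataset_label(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              dataset_label = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample ids are required (row/column names or arguments)",
         call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  out <- structure(values, dataset_label = as.character(dataset_label)[1],
                   class = c("expr_matrix", class(values)))
  validate_expr_matrix(out)
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, dataset '%s'\n",
              nrow(x), ncol(x), dataset_label(x)))
  invisible(x)
}

#' Dataset label of an expression matrix
#' @param x An `expr_matrix`.
#' @return The dataset label (character scalar); `"dataset"` if unset.
#' @export
dataset_label <- function(x) {
  lbl <- attr(x, "dataset_label")
  if (is.null(lbl)) "dataset" else lbl
}

# invariants: finite, >= 0, unique ids, dimensions consistent
validate_expr_matrix <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop("expression values must all be finite (no NA/Inf)", call. = FALSE)
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1]
    stop(sprintf("duplicated gene id: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1]
    stop(sprintf("duplicated sample id: '%s'", dup), call. = FALSE)
  }
  invisible(x)
}
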