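#' Read a gene-by-sample expression matrix from a delimited text file
#'
#' Expects the first row to be a sample header and the first column gene
#' ids. Both tab- and comma-separated dialects are supported, and the
#' decimal mark may be a point or a comma (European-style tables print
#' e.g. "22,8" for 22.8).
#'
#' @param path File path.
#' @param dialect Field separator: `"tab"` or `"comma"`.
#' @param decimal_mark Decimal mark used in the file: `"point"` or `"comma"`.
#' @param dataset_label Dataset label to attach; defaults to the file name
#'   without extension.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, dialect = c("tab", "comma"),
                        decimal_mark = c("point", "comma"),
                        dataset_label = NULL) {
  dialect <- match.arg(dialect)
  decimal_mark <- match.arg(decimal_mark)
  sep <- if (dialect == "tab") "\t" else ","
  dec <- if (decimal_mark == "point") "." else ","
  if (sep == "," && dec == ",") {
    stop("comma dialect with comma decimal mark is ambiguous; use tab",
         call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs >= 1 sample column", call. = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    stop(sprintf("duplicated gene id in '%s': '%s'", path, dup), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop(sprintf("non-numeric cell at gene '%s', sample column '%s'",
                   gene_ids[if (is.na(bad)) 1 else bad], names(vals)[j]),
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (is.null(dataset_label)) {
    dataset_label <- sub("\\.[^.]*$", "", basename(path))
  }
  expression_matrix(m, dataset_label = dataset_label)
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [read_matrix()]: the write/read round trip is value exact
#' for a given dialect (values are written with full `%.17g` precision).
#'
#' @param x Expression matrix.
#' @param path Output file path.
#' @inheritParams read_matrix
#' @param id_column Header name of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, dialect = c("tab", "comma"),
                         decimal_mark = c("point", "comma"),
                         id_column = "gene") {
  dialect <- match.arg(dialect)
  decimal_mark <- match.arg(decimal_mark)
  sep <- if (dialect == "tab") "\t" else ","
  if (sep == "," && decimal_mark == "comma") {
    stop("comma dialect with comma decimal mark is ambiguous; use tab",
         call. = FALSE)
  }
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  if (decimal_mark == "comma") chr <- sub(".", ",", chr, fixed = TRUE)
  lines <- c(paste(c(id_column, colnames(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], chr[i, ]), collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Convert raw read counts to RPKM
#'
#' RPKM (reads per kilobase of transcript per million mapped reads)
#' normalizes a count for gene length and sequencing depth:
#' `RPKM(g, s) = counts(g, s) * 1e9 / (length(g) * totals(s))`.
#'
#' @param counts Non-negative gene-by-sample count matrix with gene row
#'   names and sample column names.
#' @param lengths Named numeric vector of gene lengths in base pairs, or a
#'   two-column data frame (gene_id, length).
#' @param totals Named numeric vector of per-sample total mapped reads, or
#'   an unnamed vector in column order.
#' @param dataset_label Dataset label for the result.
#' @return An [expression_matrix()] of RPKM values.
#' @examples
#' counts <- matrix(1000, 1, 1, dimnames = list("g", "s"))
#' counts_to_rpkm(counts, c(g = 2000), c(s = 1e7))  # 50 RPKM
#' @export
counts_to_rpkm <- function(counts, lengths, totals,
                           dataset_label = "dataset") {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(as.numeric(lengths[[2]]),
                               as.character(lengths[[1]]))
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  genes <- rownames(counts)
  if (is.null(genes)) stop("counts needs gene row names", call. = FALSE)
  missing_len <- setdiff(genes, names(lengths))
  if (length(missing_len)) {
    stop(sprintf("missing gene length for: %s",
                 paste(utils::head(missing_len, 5), collapse = ", ")),
         call. = FALSE)
  }
  len <- lengths[genes]
  if (any(!is.finite(len)) || any(len < 1)) {
    stop("gene lengths must be finite and >= 1 bp", call. = FALSE)
  }
  if (!is.null(names(totals))) {
    missing_tot <- setdiff(colnames(counts), names(totals))
    if (length(missing_tot)) {
      stop(sprintf("missing mapped-read total for sample: %s",
                   missing_tot[1]), call. = FALSE)
    }
    totals <- totals[colnames(counts)]
  } else if (length(totals) != ncol(counts)) {
    stop("`totals` length must match the number of samples", call. = FALSE)
  }
  if (any(!is.finite(totals)) || any(totals <= 0)) {
    stop("per-sample totals must be finite and > 0", call. = FALSE)
  }
  rpkm <- sweep(counts * 1e9 / len, 2, totals, "/")
  expression_matrix(as.matrix(rpkm), dataset_label = dataset_label)
}

#' Combine several datasets into one pooled expression matrix
#'
#' Column-wise concatenation restricted to the intersection of gene ids.
#' Sample ids are namespaced as `"label:sample"` using each input's
#' dataset label so that samples can never silently collide.
#'
#' @param matrices List of expression matrices.
#' @param label Dataset label for the combined matrix.
#' @return An [expression_matrix()] whose sample count is the sum over
#'   the inputs and whose genes are the intersection of the inputs' genes.
#' @export
combine_datasets <- function(matrices, label = "combined") {
  if (!length(matrices)) stop("need at least one matrix", call. = FALSE)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(genes)) {
    stop("gene-id intersection across datasets is empty", call. = FALSE)
  }
  blocks <- lapply(matrices, function(m) {
    block <- unclass(m)[genes, , drop = FALSE]
    colnames(block) <- paste(dataset_label(m), colnames(block), sep = ":")
    block
  })
  combined <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(combined))) {
    stop("sample ids collide after label namespacing; use distinct dataset labels",
         call. = FALSE)
  }
  expression_matrix(combined, dataset_label = label)
}

#' Read a qPCR Ct table from a delimited text file
#'
#' Same layout as [read_matrix()] (genes as rows, samples as columns) but
#' missing entries (qPCR dropouts) are permitted and kept as `NA`. Values
#' outside the plausible 0--45 cycle range trigger a warning, not an error.
#'
#' @inheritParams read_matrix
#' @return A numeric gene-by-sample matrix of Ct values (class `ct_table`).
#' @export
read_ct_table <- function(path, dialect = c("tab", "comma"),
                          decimal_mark = c("point", "comma")) {
  dialect <- match.arg(dialect)
  decimal_mark <- match.arg(decimal_mark)
  sep <- if (dialect == "tab") "\t" else ","
  dec <- if (decimal_mark == "point") "." else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicated gene id: '%s'",
                 gene_ids[duplicated(gene_ids)][1]), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- gene_ids
  ct_table(m)
}

#' Construct a Ct table from a numeric matrix
#'
#' @param values Gene-by-sample numeric matrix of threshold-cycle values;
#'   `NA` marks qPCR dropouts.
#' @return The matrix with class `ct_table`.
#' @export
ct_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("Ct table must be a numeric matrix", call. = FALSE)
  }
  present <- values[!is.na(values)]
  if (any(!is.finite(present))) {
    stop("Ct values must be finite where present", call. = FALSE)
  }
  if (length(present) && (any(present <= 0) || any(present >= 45))) {
    warning("Ct values outside the typical (0, 45) cycle range",
            call. = FALSE)
  }
  structure(values, class = c("ct_table", class(values)))
}

#' Write a Ct table to a tab-separated file
#' @param x Ct table (gene-by-sample matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
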