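#' Per-gene expression stability statistics
#'
#' Computes the three statistics used throughout the screen for a single
#' gene's per-sample RPKM values:
#' * `mean_rpkm` -- arithmetic mean expression;
#' * `cv_percent` -- coefficient of variation, the standard deviation
#'   divided by the mean, expressed as a percentage;
#' * `mfc` -- maximum fold change, the maximum divided by the minimum
#'   value. A gene observed at zero in any sample gets `mfc = Inf`
#'   (flagged by `mfc_infinite`), so it can never pass an MFC threshold.
#'
#' @param values Numeric vector of per-sample RPKM values for one gene
#'   (>= 2 samples, all values >= 0, mean > 0).
#' @param sd_denom `"n-1"` (default) for the sample standard deviation or
#'   `"n"` for the population form. At the cohort sizes this screen is
#'   meant for (tens to thousands of samples) the difference is
#'   negligible; the switch exists so either convention can be matched.
#' @return A one-row data frame with columns `mean_rpkm`, `cv_percent`,
#'   `mfc`, `mfc_infinite`.
#' @examples
#' gene_stability(c(1, 2, 3))  # mean 2, CV 50%, MFC 3
#' @export
gene_stability <- function(values, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite (no NA)", call. = FALSE)
  }
  if (any(values < 0)) stop("RPKM values must be >= 0", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("all-zero gene: CV undefined (mean = 0)", call. = FALSE)
  s <- stats::sd(values)
  if (sd_denom == "n") {
    n <- length(values)
    s <- s * sqrt((n - 1) / n)
  }
  mn <- min(values)
  mfc <- if (mn == 0) Inf else max(values) / mn
  data.frame(mean_rpkm = m, cv_percent = 100 * s / m, mfc = mfc,
             mfc_infinite = !is.finite(mfc))
}

#' Stability table for every gene of a dataset
#'
#' Applies [gene_stability()] to each gene and ranks genes from lowest to
#' highest CV; CV ties are broken lexicographically by gene id so the
#' ranking is a deterministic function of the matrix.
#'
#' @param matrix An [expression_matrix()] (or numeric matrix with gene row
#'   names).
#' @inheritParams gene_stability
#' @return A `stability_table`: data frame with columns `rank`, `gene_id`,
#'   `mean_rpkm`, `cv_percent`, `mfc`, `mfc_infinite`, sorted by rank,
#'   with the dataset label as attribute `dataset_label`.
#' @export
stability_table <- function(matrix, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  x <- unclass(matrix)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("expression values must be finite", call. = FALSE)
  }
  n <- ncol(x)
  means <- rowMeans(x)
  if (any(means <= 0)) {
    stop(sprintf("all-zero gene: '%s' (CV undefined)",
                 rownames(x)[which(means <= 0)[1]]), call. = FALSE)
  }
  sds <- sqrt(rowSums((x - means)^2) / (n - 1))
  if (sd_denom == "n") sds <- sds * sqrt((n - 1) / n)
  mins <- do.call(pmin, as.data.frame(x))
  maxs <- do.call(pmax, as.data.frame(x))
  mfc <- ifelse(mins == 0, Inf, maxs / mins)
  tab <- data.frame(gene_id = rownames(x), mean_rpkm = means,
                    cv_percent = 100 * sds / means, mfc = mfc,
                    mfc_infinite = !is.finite(mfc),
                    stringsAsFactors = FALSE, row.names = NULL)
  new_stability_table(tab, dataset_label(matrix))
}

# rank by ascending CV, ties broken by gene id; shared by constructors
new_stability_table <- function(tab, label) {
  ord <- order(tab$cv_percent, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(tab, dataset_label = label,
            class = c("stability_table", "data.frame"))
}

#' Build a stability table from precomputed per-gene statistics
#'
#' Used when the per-gene mean/CV/MFC values are available as a table
#' (for instance transcribed from a publication) rather than recomputed
#' from an expression matrix. Ranks exactly as [stability_table()].
#'
#' @param df Data frame with columns `gene_id`, `mean_rpkm`, `cv_percent`,
#'   `mfc`.
#' @param dataset_label Dataset label.
#' @return A `stability_table`.
#' @export
as_stability_table <- function(df, dataset_label = "dataset") {
  need <- c("gene_id", "mean_rpkm", "cv_percent", "mfc")
  if (!all(need %in% names(df))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  tab <- data.frame(gene_id = as.character(df$gene_id),
                    mean_rpkm = as.numeric(df$mean_rpkm),
                    cv_percent = as.numeric(df$cv_percent),
                    mfc = as.numeric(df$mfc),
                    stringsAsFactors = FALSE)
  tab$mfc_infinite <- !is.finite(tab$mfc)
  new_stability_table(tab, dataset_label)
}

#' Median and range summary of a gene panel's stability
#'
#' Summarizes the CV and MFC of a panel of genes (for instance the
#' conventional qPCR control genes) within one stability table. The
#' median is the middle value for odd panel sizes and the mean of the two
#' central values for even sizes (the usual definition).
#'
#' @param table A `stability_table`.
#' @param genes Character vector of gene ids; all must be present.
#' @return A one-row data frame: `n_genes`, `median_cv`, `cv_min`,
#'   `cv_max`, `median_mfc`, `mfc_min`, `mfc_max`.
#' @export
panel_summary <- function(table, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene panel", call. = FALSE)
  missing <- setdiff(genes, table$gene_id)
  if (length(missing)) {
    stop(sprintf("panel genes absent from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sub <- table[match(genes, table$gene_id), ]
  data.frame(n_genes = length(genes),
             median_cv = stats::median(sub$cv_percent),
             cv_min = min(sub$cv_percent), cv_max = max(sub$cv_percent),
             median_mfc = stats::median(sub$mfc),
             mfc_min = min(sub$mfc), mfc_max = max(sub$mfc))
}

#' Rolling-window CV quantile curves across the transcriptome
#'
#' Genes are ranked by mean RPKM; over a sliding window of `window`
#' consecutively ranked genes the requested quantiles of CV are computed,
#' giving background curves of expression variability as a function of
#' expression level. A gene's CV can then be placed against genes of
#' comparable abundance with [quantile_position()].
#'
#' @param matrix Expression matrix (gene count >= `window`).
#' @param window Number of ranked genes per window (default 2000).
#' @param levels Quantile levels as percentages (default 5, 25, 50, 75).
#' @param step Step between successive window centers in genes; the
#'   default 1 is fully rolling.
#' @return A `quantile_curves` data frame: `center_mean_rpkm` plus one
#'   `q<level>` column per level; attributes `window`, `levels`, `step`.
#' @export
quantile_curves <- function(matrix, window = 2000, levels = c(5, 25, 50, 75),
                            step = 1) {
  tab <- stability_table(matrix)
  quantile_curves_from_table(tab, window = window, levels = levels,
                             step = step)
}

# core rolling computation on a stability_table (also used by tests)
quantile_curves_from_table <- function(tab, window = 2000,
                                       levels = c(5, 25, 50, 75), step = 1) {
  levels <- sort(as.numeric(levels))
  if (any(levels < 0 | levels > 100)) {
    stop("quantile levels must lie in [0, 100]", call. = FALSE)
  }
  n <- nrow(tab)
  if (window > n) {
    stop(sprintf("window (%d) exceeds gene count (%d)", window, n),
         call. = FALSE)
  }
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  ord <- order(tab$mean_rpkm, tab$gene_id)
  means <- tab$mean_rpkm[ord]
  cvs <- tab$cv_percent[ord]
  starts <- seq.int(1L, n - window + 1L, by = step)
  qs <- t(vapply(starts, function(i) {
    idx <- i:(i + window - 1L)
    c(mean(means[idx]), stats::quantile(cvs[idx], probs = levels / 100,
                                        names = FALSE))
  }, numeric(1 + length(levels))))
  out <- as.data.frame(qs)
  names(out) <- c("center_mean_rpkm", paste0("q", levels))
  structure(out, window = window, levels = levels, step = step,
            class = c("quantile_curves", "data.frame"))
}

#' Place a gene's CV against the background quantile curves
#'
#' Finds the window whose center mean RPKM is nearest the gene's mean and
#' returns the smallest quantile level whose curve CV is at or above the
#' gene's CV (e.g. a return of 5 means "at or below the 5th-quantile
#' curve"; a gene holding a window's exact median CV classifies at the
#' 50% level). A gene more variable than every curve returns `Inf`.
#' Genes outside the
#' curves' expression support are compared against the nearest window,
#' with a warning.
#'
#' @param gene_id Gene to classify.
#' @param curves A `quantile_curves` object.
#' @param table The `stability_table` the gene belongs to.
#' @return The classification level (one of the curve levels, or `Inf`).
#' @export
quantile_position <- function(gene_id, curves, table) {
  row <- table[table$gene_id == gene_id, ]
  if (!nrow(row)) stop(sprintf("gene '%s' not in table", gene_id),
                       call. = FALSE)
  centers <- curves$center_mean_rpkm
  if (row$mean_rpkm < min(centers) || row$mean_rpkm > max(centers)) {
    warning(sprintf("gene '%s' outside curve support; using nearest window",
                    gene_id), call. = FALSE)
  }
  w <- which.min(abs(centers - row$mean_rpkm))
  levels <- attr(curves, "levels")
  curve_cvs <- as.numeric(curves[w, paste0("q", levels)])
  above <- which(curve_cvs >= row$cv_percent)
  if (!length(above)) return(Inf)
  levels[above[1]]
}

#' Export a stability table as TSV
#'
#' Columns `(rank, gene, mean, cv_percent, mfc)`, one row per gene in
#' rank order, mirroring the layout of published control-gene tables.
#'
#' @param table A `stability_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stability_table <- function(table, path) {
  out <- data.frame(rank = table$rank, gene = table$gene_id,
                    mean = table$mean_rpkm, cv_percent = table$cv_percent,
                    mfc = table$mfc)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
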