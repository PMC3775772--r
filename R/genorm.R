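#' Convert Ct values to relative quantities
#'
#' The standard efficiency transform used ahead of GeNorm: for each gene
#' the quantity is `efficiency^(minCt - Ct)`, so the sample with the
#' lowest Ct (most template) gets quantity 1 and every other sample a
#' value in (0, 1]. A perfect assay doubles the template each cycle
#' (efficiency 2).
#'
#' @param ct Gene-by-sample Ct matrix ([ct_table()]); genes with any
#'   missing Ct are excluded with a warning.
#' @param efficiency Amplification efficiency, a scalar applied to every
#'   gene or a named per-gene vector (default 2). An efficiency of 1
#'   degenerates to all-ones quantities and is warned about.
#' @return A gene-by-sample matrix of strictly positive relative
#'   quantities with per-gene maximum 1.
#' @export
ct_to_quantity <- function(ct, efficiency = 2) {
  x <- unclass(ct)
  complete <- !apply(x, 1, anyNA)
  if (!all(complete)) {
    warning(sprintf("excluding gene(s) with missing Ct: %s",
                    paste(rownames(x)[!complete], collapse = ", ")),
            call. = FALSE)
    x <- x[complete, , drop = FALSE]
  }
  if (!nrow(x)) stop("no gene has a complete Ct row", call. = FALSE)
  if (is.null(names(efficiency))) {
    eff <- rep_len(efficiency, nrow(x))
  } else {
    eff <- efficiency[rownames(x)]
    if (anyNA(eff)) stop("missing efficiency for some genes", call. = FALSE)
  }
  if (any(eff <= 0)) stop("efficiency must be > 0", call. = FALSE)
  if (any(eff == 1)) {
    warning("efficiency 1 is degenerate: all quantities become 1",
            call. = FALSE)
  }
  q <- eff^(apply(x, 1, min) - x)
  dimnames(q) <- dimnames(x)
  q
}

#' GeNorm pairwise variation between two genes
#'
#' The standard deviation (n - 1 denominator) across samples of the
#' log2 ratio of the two genes' relative quantities. Two genes whose
#' quantities are proportional across samples have pairwise variation 0;
#' the statistic is symmetric in its gene arguments and invariant under
#' per-sample rescaling of all genes.
#'
#' @param quantities Gene-by-sample matrix of strictly positive relative
#'   quantities.
#' @param gene_j,gene_k Gene ids (rows of `quantities`).
#' @return Non-negative scalar.
#' @export
pairwise_variation <- function(quantities, gene_j, gene_k) {
  if (!all(c(gene_j, gene_k) %in% rownames(quantities))) {
    stop("both genes must be present", call. = FALSE)
  }
  if (ncol(quantities) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(quantities[c(gene_j, gene_k), ] <= 0)) {
    stop("quantities must be strictly positive", call. = FALSE)
  }
  stats::sd(log2(quantities[gene_j, ] / quantities[gene_k, ]))
}

#' GeNorm expression-consistency M values
#'
#' For each gene j, `M(j)` is the arithmetic mean of the pairwise
#' variations between j and every other gene in the panel. Lower M means
#' more consistent expression relative to the rest of the panel. M is
#' invariant under per-gene and per-sample scalar rescaling of the
#' quantities.
#'
#' @param quantities Gene-by-sample matrix of strictly positive relative
#'   quantities (>= 2 genes, >= 2 samples).
#' @return A data frame `(gene_id, m)` sorted by ascending M (ties by
#'   gene id).
#' @export
m_values <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 2) stop("need >= 2 genes", call. = FALSE)
  if (ncol(q) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(q <= 0) || any(!is.finite(q))) {
    stop("quantities must be strictly positive and finite", call. = FALSE)
  }
  lg <- log2(q)
  n <- nrow(q)
  v <- matrix(0, n, n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      v[j, k] <- v[k, j] <- stats::sd(lg[j, ] - lg[k, ])
    }
  }
  m <- rowSums(v) / (n - 1)
  out <- data.frame(gene_id = rownames(q), m = m, stringsAsFactors = FALSE)
  out <- out[order(out$m, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' GeNorm stepwise exclusion ranking
#'
#' Repeatedly removes the gene with the highest M value and recomputes M
#' on the remainder until two genes are left. Ties at removal are broken
#' by excluding the lexicographically larger gene id, making the order
#' deterministic.
#'
#' @inheritParams m_values
#' @return A list with `removed` (gene ids in removal order, least
#'   stable first) and `final_pair` (the two genes retained).
#' @export
stepwise_ranking <- function(quantities) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3) stop("need >= 3 genes for stepwise exclusion",
                        call. = FALSE)
  removed <- character(0)
  while (nrow(q) > 2) {
    m <- m_values(q)
    worst <- m$gene_id[m$m == max(m$m)]
    worst <- sort(worst, decreasing = TRUE)[1]
    removed <- c(removed, worst)
    q <- q[setdiff(rownames(q), worst), , drop = FALSE]
  }
  list(removed = removed, final_pair = sort(rownames(q)))
}
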