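#' Candidate selection criteria
#'
#' Thresholds for the stability screen: a candidate control gene must
#' have CV strictly below `cv_max` percent and a finite MFC strictly
#' below `mfc_max`, within one of two expression strata defined by mean
#' RPKM: "high" (mean > `stratum_mid`) or "mid"
#' (`stratum_low` < mean <= `stratum_mid`). Genes at or below
#' `stratum_low` are considered too weakly expressed to serve as
#' controls.
#'
#' @param cv_max CV threshold in percent (default 25).
#' @param mfc_max MFC threshold (default 5).
#' @param stratum_low Lower mean-RPKM bound for any candidate (default 25).
#' @param stratum_mid Boundary between the mid and high strata (default 100).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(cv_max = 25, mfc_max = 5,
                               stratum_low = 25, stratum_mid = 100) {
  if (cv_max <= 0) stop("cv_max must be > 0", call. = FALSE)
  if (mfc_max < 1) stop("mfc_max must be >= 1", call. = FALSE)
  if (stratum_low >= stratum_mid) {
    stop("stratum_low must be < stratum_mid", call. = FALSE)
  }
  structure(list(cv_max = cv_max, mfc_max = mfc_max,
                 stratum_low = stratum_low, stratum_mid = stratum_mid),
            class = "selection_criteria")
}

#' Select candidate control genes within an expression stratum
#'
#' Filters a stability table to genes with `cv_percent < cv_max`, finite
#' `mfc < mfc_max`, and mean RPKM in the requested stratum, returned in
#' ascending CV order (re-ranked within the selection). An empty result
#' is valid.
#'
#' @param table A `stability_table`.
#' @param criteria A [selection_criteria()] object.
#' @param stratum `"high"` (mean > `stratum_mid`) or `"mid"`
#'   (`stratum_low` < mean <= `stratum_mid`).
#' @return A data frame `(rank, gene_id, mean_rpkm, cv_percent, mfc)` of
#'   selected genes.
#' @export
select_candidates <- function(table, criteria = selection_criteria(),
                              stratum = c("high", "mid")) {
  stratum <- match.arg(stratum)
  keep <- table$cv_percent < criteria$cv_max &
    is.finite(table$mfc) & table$mfc < criteria$mfc_max
  keep <- keep & if (stratum == "high") {
    table$mean_rpkm > criteria$stratum_mid
  } else {
    table$mean_rpkm > criteria$stratum_low &
      table$mean_rpkm <= criteria$stratum_mid
  }
  sub <- table[keep, c("gene_id", "mean_rpkm", "cv_percent", "mfc"),
               drop = FALSE]
  sub <- sub[order(sub$cv_percent, sub$gene_id), , drop = FALSE]
  rownames(sub) <- NULL
  cbind(rank = seq_len(nrow(sub)), sub)
}

#' Score candidate genes across multiple datasets
#'
#' For each gene, each dataset contributes two pass flags: one for
#' `CV < cv_max` and one for finite `MFC < mfc_max`. The score is the
#' total number of raised flags divided by 2, so a gene passing both
#' criteria in all of 10 datasets scores 10.0 and half-integer scores
#' arise when only one criterion passes in some dataset. Genes are
#' ranked by descending score; ties are broken by ascending mean CV
#' across the datasets, then by gene id.
#'
#' @param tables List of `stability_table` objects (one per dataset).
#' @param criteria A [selection_criteria()] object (only `cv_max` and
#'   `mfc_max` are used).
#' @param genes Character vector of gene ids to score. A gene missing
#'   from a dataset contributes 0 passes there, with a warning.
#' @return A `score_card` data frame `(rank, gene_id, score, cv_passes,
#'   mfc_passes, mean_cv)` sorted by rank; the per-dataset flag matrices
#'   are kept in attributes `cv_flags` and `mfc_flags`.
#' @export
score_across_datasets <- function(tables, criteria = selection_criteria(),
                                  genes) {
  if (!length(tables)) stop("need at least one dataset", call. = FALSE)
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  nd <- length(tables)
  labels <- vapply(seq_along(tables), function(i) {
    lbl <- attr(tables[[i]], "dataset_label")
    if (is.null(lbl)) paste0("dataset", i) else lbl
  }, character(1))
  cv_flags <- matrix(FALSE, length(genes), nd,
                     dimnames = list(genes, labels))
  mfc_flags <- cv_flags
  cv_vals <- matrix(NA_real_, length(genes), nd)
  for (d in seq_len(nd)) {
    tab <- tables[[d]]
    idx <- match(genes, tab$gene_id)
    if (anyNA(idx)) {
      warning(sprintf("gene(s) missing from dataset '%s': %s (0 passes there)",
                      labels[d],
                      paste(genes[is.na(idx)], collapse = ", ")),
              call. = FALSE)
    }
    hit <- !is.na(idx)
    cv <- tab$cv_percent[idx[hit]]
    mfc <- tab$mfc[idx[hit]]
    cv_flags[hit, d] <- cv < criteria$cv_max
    mfc_flags[hit, d] <- is.finite(mfc) & mfc < criteria$mfc_max
    cv_vals[hit, d] <- cv
  }
  cv_passes <- rowSums(cv_flags)
  mfc_passes <- rowSums(mfc_flags)
  mean_cv <- rowMeans(cv_vals, na.rm = TRUE)
  card <- data.frame(gene_id = genes, score = (cv_passes + mfc_passes) / 2,
                     cv_passes = cv_passes, mfc_passes = mfc_passes,
                     mean_cv = mean_cv, stringsAsFactors = FALSE)
  ord <- order(-card$score, card$mean_cv, card$gene_id)
  card <- card[ord, , drop = FALSE]
  rownames(card) <- NULL
  card <- cbind(rank = seq_len(nrow(card)), card)
  structure(card, cv_flags = cv_flags, mfc_flags = mfc_flags,
            n_datasets = nd, class = c("score_card", "data.frame"))
}

#' Recovery of planted stable genes from a score card
#'
#' Test harness for synthetic studies: given the hidden class labels of a
#' planted-gene simulation, computes precision and recall of the
#' "stable" class among the top `top_k` genes of the score card.
#'
#' @param scorecard A `score_card` from [score_across_datasets()].
#' @param labels Data frame with columns `gene_id` and `class`
#'   (`"stable"` / `"variable"`), covering all scored genes.
#' @param top_k Number of top-ranked genes to take (defaults to the
#'   number of planted stable genes among the scored genes).
#' @return A one-row data frame: `top_k`, `n_stable`, `true_positives`,
#'   `precision`, `recall`.
#' @export
recover_planted <- function(scorecard, labels, top_k = NULL) {
  cls <- labels$class[match(scorecard$gene_id, labels$gene_id)]
  if (anyNA(cls)) stop("labels do not cover all scored genes", call. = FALSE)
  n_stable <- sum(cls == "stable")
  if (is.null(top_k)) top_k <- n_stable
  if (top_k > nrow(scorecard)) {
    stop("top_k exceeds the number of scored genes", call. = FALSE)
  }
  tp <- sum(cls[seq_len(top_k)] == "stable")
  data.frame(top_k = top_k, n_stable = n_stable, true_positives = tp,
             precision = tp / top_k,
             recall = if (n_stable == 0) NA_real_ else tp / n_stable)
}

#' Export a score card as TSV
#' @param scorecard A `score_card`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_card <- function(scorecard, path) {
  utils::write.table(as.data.frame(scorecard), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
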