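#' Run the full control-gene discovery screen
#'
#' Orchestrates the end-to-end screen over a set of datasets: per-dataset
#' stability tables, a pooled combined-dataset table, stratified
#' candidate selection on the discovery dataset, cross-dataset criterion
#' scoring, background CV quantile curves on the combined matrix, panel
#' summaries for any user-supplied gene panels, and a machine-readable
#' run manifest. The first dataset is the discovery dataset from which
#' candidates are selected; all datasets contribute to scoring.
#'
#' The run is deterministic: given the same inputs and parameters the
#' report bundle is byte-identical.
#'
#' @param datasets Named list of expression matrices, or of file paths to
#'   be read with [read_matrix()]. Names become dataset labels for paths.
#' @param output_dir Directory for the report bundle; created if absent.
#'   `NULL` skips all file output and just returns the results.
#' @param criteria A [selection_criteria()] object.
#' @param panels Named list of gene-id vectors to summarize with
#'   [panel_summary()] (e.g. a panel of conventional control genes).
#' @param score_genes Genes to score across datasets; defaults to the
#'   union of the stratified candidates from the discovery dataset.
#' @param quantile_window Window size for [quantile_curves()]; defaults
#'   to `min(2000, gene count)`. `NA` skips the curves.
#' @param quantile_step Step between window centers (default: fully
#'   rolling for small matrices, 25 for transcriptome-scale ones).
#' @param dialect,decimal_mark Passed to [read_matrix()] for path inputs.
#' @param verbose Log stage-by-stage gene/sample counts via [message()].
#' @return A list: `tables` (per-dataset stability tables), `combined`
#'   (pooled table), `candidates` (`high`/`mid` data frames),
#'   `scorecard`, `curves`, `panel_summaries`, `manifest`. Invisibly.
#' @export
run_screen <- function(datasets, output_dir = NULL,
                       criteria = selection_criteria(), panels = list(),
                       score_genes = NULL, quantile_window = NULL,
                       quantile_step = NULL,
                       dialect = "tab", decimal_mark = "point",
                       verbose = TRUE) {
  if (!length(datasets)) stop("need at least one dataset", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  mats <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (is.character(d)) {
      read_matrix(d, dialect = dialect, decimal_mark = decimal_mark,
                  dataset_label = names(datasets)[i])
    } else d
  })
  labels <- vapply(mats, dataset_label, character(1))
  if (anyDuplicated(labels)) {
    stop("dataset labels must be unique", call. = FALSE)
  }
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  emit <- function(obj, file, writer) {
    if (!is.null(output_dir)) writer(obj, file.path(output_dir, file))
  }

  say("stability: %d dataset(s)", length(mats))
  tables <- lapply(mats, stability_table)
  names(tables) <- labels
  for (lbl in labels) {
    emit(tables[[lbl]], sprintf("stability_%s.tsv", lbl),
         write_stability_table)
    say("  %s: %d genes x %d samples", lbl, nrow(tables[[lbl]]),
        ncol(mats[[match(lbl, labels)]]))
  }

  combined_tab <- NULL
  combined_mat <- NULL
  if (length(mats) > 1) {
    combined_mat <- combine_datasets(mats, label = "combined")
    combined_tab <- stability_table(combined_mat)
    emit(combined_tab, "stability_combined.tsv", write_stability_table)
    say("combined: %d genes x %d samples", nrow(combined_tab),
        ncol(combined_mat))
  } else {
    combined_mat <- mats[[1]]
    combined_tab <- tables[[1]]
  }

  discovery <- tables[[1]]
  candidates <- list(high = select_candidates(discovery, criteria, "high"),
                     mid = select_candidates(discovery, criteria, "mid"))
  say("selection (discovery = %s): %d high-stratum, %d mid-stratum candidates",
      labels[1], nrow(candidates$high), nrow(candidates$mid))
  emit(candidates$high, "candidates_high.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))
  emit(candidates$mid, "candidates_mid.tsv",
       function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE))

  if (is.null(score_genes)) {
    score_genes <- union(candidates$high$gene_id, candidates$mid$gene_id)
  }
  scorecard <- NULL
  if (length(score_genes)) {
    scorecard <- score_across_datasets(tables, criteria, score_genes)
    emit(scorecard, "scorecard.tsv", write_score_card)
    say("scoring: %d genes across %d datasets; top score %.1f",
        nrow(scorecard), length(tables), scorecard$score[1])
  }

  n_genes <- nrow(combined_tab)
  if (is.null(quantile_window)) quantile_window <- min(2000L, n_genes)
  curves <- NULL
  if (!is.na(quantile_window) && quantile_window >= 2) {
    if (is.null(quantile_step)) {
      quantile_step <- if (n_genes > 5000) 25L else 1L
    }
    curves <- quantile_curves_from_table(combined_tab,
                                         window = quantile_window,
                                         step = quantile_step)
    emit(curves, "quantile_curves.tsv",
         function(x, p) utils::write.table(as.data.frame(x), p, sep = "\t",
                                           quote = FALSE, row.names = FALSE))
    say("quantile curves: window %d, %d window position(s)",
        quantile_window, nrow(curves))
  }

  panel_summaries <- lapply(panels, function(genes) {
    per_ds <- lapply(tables, panel_summary, genes = genes)
    out <- cbind(dataset = c(names(tables), "combined"),
                 do.call(rbind, c(per_ds,
                                  list(panel_summary(combined_tab, genes)))))
    rownames(out) <- NULL
    out
  })
  for (nm in names(panel_summaries)) {
    emit(panel_summaries[[nm]], sprintf("panel_%s.tsv", nm),
         function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE))
  }

  manifest <- list(
    datasets = labels,
    n_genes = vapply(mats, nrow, integer(1)),
    n_samples = vapply(mats, ncol, integer(1)),
    criteria = unclass(criteria),
    quantile_window = quantile_window,
    score_genes = score_genes,
    package = "ctrlscreen",
    version = as.character(utils::packageVersion("ctrlscreen")))
  if (!is.null(output_dir)) {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(tables = tables, combined = combined_tab,
                 candidates = candidates, scorecard = scorecard,
                 curves = curves, panel_summaries = panel_summaries,
                 manifest = manifest))
}

#' Run the qPCR validation stage
#'
#' Given a Ct table and the matching expression matrix, computes the
#' GeNorm M value of every assayed gene, the Spearman correlation
#' between the target's RPKM and its dCt under each candidate control,
#' and the RQ panel statistics (CV%, MFC of the relative quantification)
#' for each target/control pair.
#'
#' @param matrix Expression matrix sharing samples with `ct`.
#' @param ct Gene-by-sample Ct table.
#' @param target Target gene id (the gene whose expression is being
#'   quantified).
#' @param controls Character vector of candidate control gene ids.
#' @param calibrator_samples Calibrator sample id(s) for RQ.
#' @param output_dir Optional directory for TSV reports.
#' @return A list: `m_values` (GeNorm table), `correlations`
#'   (per-control rho), `rq_stats` (per-control RQ CV%/MFC),
#'   `rq_tables` (per-control per-sample RQ). Invisibly.
#' @export
run_validation <- function(matrix, ct, target, controls,
                           calibrator_samples, output_dir = NULL) {
  q <- ct_to_quantity(ct)
  m_tab <- m_values(q)
  correlations <- correlation_validation(matrix, ct, target, controls)
  rq_list <- lapply(controls, function(ctrl) {
    rq_panel(ct, target, ctrl, calibrator_samples)
  })
  names(rq_list) <- controls
  rq_stats <- data.frame(
    control_gene_id = controls,
    rq_cv_percent = vapply(rq_list, function(r) r$cv_percent, numeric(1)),
    rq_mfc = vapply(rq_list, function(r) r$mfc, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(rq_stats) <- NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.table(m_tab, file.path(output_dir, "genorm_m.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(correlations,
                       file.path(output_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rq_stats, file.path(output_dir, "rq_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(m_values = m_tab, correlations = correlations,
                 rq_stats = rq_stats,
                 rq_tables = lapply(rq_list, function(r) r$rq)))
}
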