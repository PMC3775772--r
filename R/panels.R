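#' Bundled control-gene stability panels
#'
#' Per-gene stability statistics (mean RPKM, CV%, MFC) for three
#' reference gene panels, as published for a 55-sample AML/ALL RNA-seq
#' cohort (Leucegene) and a combined pan-cancer TCGA cohort of 1933
#' samples:
#' * `"conventional"` -- 19 control genes in common qPCR use (GAPDH,
#'   ACTB, TBP, ...), with statistics in both cohorts;
#' * `"microarray"` -- 12 candidates previously proposed from microarray
#'   meta-analysis (mostly ribosomal protein genes), both cohorts;
#' * `"candidates"` -- the stable candidates that emerged from the
#'   leukemia-cohort screen, with their expression stratum (`high` for
#'   mean RPKM > 100, `mid` for 25--100).
#'
#' These tables serve as worked inputs for [panel_summary()],
#' [as_stability_table()] and [select_candidates()]; they are printed
#' summary statistics, not expression matrices.
#'
#' @param which Panel name.
#' @return A data frame; column names follow the fixture files
#'   (`gene`, per-cohort `mean`/`cv`/`mfc`, and for `"candidates"` a
#'   `stratum` column).
#' @export
published_panel <- function(which = c("conventional", "microarray",
                                      "candidates")) {
  which <- match.arg(which)
  file <- switch(which,
                 conventional = "conventional_controls_stability.tsv",
                 microarray = "microarray_candidates_stability.tsv",
                 candidates = "leucegene_candidates_stability.tsv")
  path <- system.file("extdata", file, package = "ctrlscreen",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Stability table from a bundled panel, for one cohort
#'
#' Convenience wrapper turning a [published_panel()] into a ranked
#' `stability_table` for the requested cohort's columns.
#'
#' @param which Panel name (`"conventional"` or `"microarray"`).
#' @param cohort `"leucegene"` or `"tcga"`.
#' @return A `stability_table`.
#' @export
panel_stability_table <- function(which = c("conventional", "microarray"),
                                  cohort = c("leucegene", "tcga")) {
  which <- match.arg(which)
  cohort <- match.arg(cohort)
  df <- published_panel(which)
  as_stability_table(
    data.frame(gene_id = df$gene,
               mean_rpkm = df[[paste0(cohort, "_mean")]],
               cv_percent = df[[paste0(cohort, "_cv")]],
               mfc = df[[paste0(cohort, "_mfc")]]),
    dataset_label = paste(which, cohort, sep = "_"))
}
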