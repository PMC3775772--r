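#' Delta Ct between target and control gene
#'
#' `dCt = Ct(target) - Ct(control)`, the within-sample normalization step
#' of the ddCt method. Vectorized over samples; missing Ct values
#' propagate as `NA`.
#'
#' @param ct_target,ct_control Numeric Ct values (cycles).
#' @return `ct_target - ct_control`, in cycles.
#' @export
delta_ct <- function(ct_target, ct_control) {
  ct_target - ct_control
}

#' Relative quantification by the ddCt method
#'
#' `ddCt = dCt(sample) - dCt(calibrator)` and `RQ = 2^(-ddCt)`: the
#' expression of the target relative to the calibrator sample, assuming
#' perfect doubling per cycle. The calibrator dCt may itself be a mean
#' over calibrator replicates.
#'
#' @param dct_sample dCt of the test sample(s), in cycles.
#' @param dct_calibrator dCt of the calibrator (scalar), in cycles.
#' @return A data frame with columns `dct`, `ddct`, `rq`.
#' @examples
#' relative_quantification(5, 5)  # RQ 1
#' relative_quantification(4, 5)  # ddCt -1, RQ 2
#' @export
relative_quantification <- function(dct_sample, dct_calibrator) {
  if (length(dct_calibrator) != 1 || !is.finite(dct_calibrator)) {
    stop("calibrator dCt must be a single finite value", call. = FALSE)
  }
  ddct <- dct_sample - dct_calibrator
  data.frame(dct = dct_sample, ddct = ddct, rq = 2^(-ddct))
}

#' Per-sample RQ panel with CV/MFC summary
#'
#' Runs the full ddCt workflow on a Ct table for one target/control gene
#' pair: per-sample dCt, calibration against the mean dCt of the
#' calibrator sample(s), per-sample RQ, and the stability statistics
#' (CV%, MFC) of the RQ values. By default the calibrator samples (whose
#' RQ is 1 by construction when there is a single calibrator) are
#' excluded from the CV/MFC summary so the summary reflects the test
#' samples only.
#'
#' @param ct Gene-by-sample Ct table.
#' @param target Target gene id.
#' @param control Control (normalizer) gene id.
#' @param calibrator_samples Sample id(s) of the calibrator; the
#'   calibrator dCt is their mean dCt.
#' @param include_calibrator Include the calibrator samples in the CV/MFC
#'   summary (default `FALSE`).
#' @return A list: `rq` (data frame `sample_id`, `dct`, `ddct`, `rq`),
#'   `cv_percent`, `mfc`.
#' @export
rq_panel <- function(ct, target, control, calibrator_samples,
                     include_calibrator = FALSE) {
  x <- unclass(ct)
  for (g in c(target, control)) {
    if (!g %in% rownames(x)) {
      stop(sprintf("gene '%s' missing from Ct table", g), call. = FALSE)
    }
  }
  missing_cal <- setdiff(calibrator_samples, colnames(x))
  if (length(missing_cal)) {
    stop(sprintf("calibrator sample(s) missing: %s",
                 paste(missing_cal, collapse = ", ")), call. = FALSE)
  }
  dct <- delta_ct(x[target, ], x[control, ])
  if (anyNA(dct)) {
    stop("missing Ct values for target/control in some samples",
         call. = FALSE)
  }
  dct_cal <- mean(dct[calibrator_samples])
  rq <- relative_quantification(dct, dct_cal)
  rq <- cbind(sample_id = colnames(x), rq)
  rownames(rq) <- NULL
  keep <- if (include_calibrator) rq$sample_id else
    setdiff(rq$sample_id, calibrator_samples)
  stats <- gene_stability(rq$rq[rq$sample_id %in% keep])
  list(rq = rq, cv_percent = stats$cv_percent, mfc = stats$mfc)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties: both vectors are ranked
#' (ties receiving their average rank) and the Pearson correlation of the
#' rank vectors is returned. Invariant under strictly monotone transforms
#' of either input.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho in `[-1, 1]`; `NA` with a warning when either
#'   input is constant (correlation undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 paired observations", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Correlate RNA-seq expression with qPCR dCt for candidate controls
#'
#' For each candidate control gene, computes the Spearman correlation
#' between the target gene's RPKM (from the expression matrix) and its
#' dCt normalized to that control (from the Ct table) across the samples
#' shared by both tables. A good control preserves the monotone
#' RPKM-to-dCt relationship (rho near -1: higher RPKM, lower dCt); a
#' variable control degrades it.
#'
#' @param matrix Expression matrix containing the target gene.
#' @param ct Ct table containing the target and control genes.
#' @param target Target gene id.
#' @param controls Character vector of control gene ids.
#' @return A data frame `(control_gene_id, rho, n)`.
#' @export
correlation_validation <- function(matrix, ct, target, controls) {
  shared <- intersect(colnames(matrix), colnames(ct))
  if (length(shared) < 3) {
    stop("need >= 3 samples shared between expression matrix and Ct table",
         call. = FALSE)
  }
  if (!target %in% rownames(matrix)) {
    stop(sprintf("target '%s' missing from expression matrix", target),
         call. = FALSE)
  }
  if (!target %in% rownames(ct)) {
    stop(sprintf("target '%s' missing from Ct table", target), call. = FALSE)
  }
  rpkm <- unclass(matrix)[target, shared]
  out <- lapply(controls, function(ctrl) {
    if (!ctrl %in% rownames(ct)) {
      stop(sprintf("control '%s' missing from Ct table", ctrl),
           call. = FALSE)
    }
    dct <- delta_ct(unclass(ct)[target, shared], unclass(ct)[ctrl, shared])
    data.frame(control_gene_id = ctrl, rho = spearman_rho(rpkm, dct),
               n = length(shared), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
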