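#' Configuration for the synthetic multi-dataset study generator
#'
#' Defines the study conditions emulated by the generator: multi-cohort
#' RPKM matrices whose per-gene means span a log-uniform range and whose
#' per-gene dispersion is set by class -- a planted minority of "stable"
#' genes at a low CV target and a majority of "variable" genes with CVs
#' drawn over a wide range -- plus a log-linear qPCR observation model
#' that maps RPKM to Ct.
#'
#' Per-gene values are log-normal: for a target CV (as a fraction), the
#' log-scale standard deviation is `sigma = sqrt(log(1 + CV^2))`, since
#' for a log-normal law `CV^2 = exp(sigma^2) - 1`, and the log-mean is
#' chosen so the arithmetic mean equals the gene's drawn mean RPKM.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_samples Samples per dataset (default 100).
#' @param n_datasets Number of datasets (cohorts) in a study (default 10).
#' @param frac_stable Fraction of genes planted as stable (default 0.05).
#' @param mean_log2_range Bounds of the log2 mean RPKM, drawn uniformly
#'   (default `c(2, 12)`, i.e. means from 4 to 4096 RPKM, covering the
#'   few-to-thousands RPKM range typical of expressed genes).
#' @param stable_cv_target CV target of planted stable genes, in percent
#'   (default 10).
#' @param variable_cv_range CV range of variable genes, in percent
#'   (default `c(40, 120)`); its lower bound must exceed
#'   `stable_cv_target` so the planted classes are separable.
#' @param ct_intercept Ct at 1 RPKM, in cycles (default 32).
#' @param ct_slope Cycles per log2 RPKM (default 1: perfect doubling
#'   efficiency).
#' @param ct_noise_sd Gaussian measurement noise on Ct, in cycles
#'   (default 0.15).
#' @param seed Master seed; per-dataset substreams are spawned by fixed
#'   offsets so adding datasets never perturbs earlier ones.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_samples = 100,
                             n_datasets = 10, frac_stable = 0.05,
                             mean_log2_range = c(2, 12),
                             stable_cv_target = 10,
                             variable_cv_range = c(40, 120),
                             ct_intercept = 32, ct_slope = 1,
                             ct_noise_sd = 0.15, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              n_datasets = n_datasets, frac_stable = frac_stable,
              mean_log2_range = as.numeric(mean_log2_range),
              stable_cv_target = stable_cv_target,
              variable_cv_range = as.numeric(variable_cv_range),
              ct_intercept = ct_intercept, ct_slope = ct_slope,
              ct_noise_sd = ct_noise_sd, seed = as.integer(seed))
  nums <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (anyNA(nums) || any(!is.finite(nums))) {
    stop("synthetic config values must be finite", call. = FALSE)
  }
  if (cfg$n_genes < 1 || cfg$n_samples < 1 || cfg$n_datasets < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (cfg$frac_stable < 0 || cfg$frac_stable > 1) {
    stop("frac_stable must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  if (length(cfg$mean_log2_range) != 2 ||
      diff(cfg$mean_log2_range) < 0) {
    stop("mean_log2_range must be an increasing pair", call. = FALSE)
  }
  if (length(cfg$variable_cv_range) != 2 ||
      diff(cfg$variable_cv_range) < 0) {
    stop("variable_cv_range must be an increasing pair", call. = FALSE)
  }
  if (cfg$stable_cv_target >= cfg$variable_cv_range[1]) {
    stop("stable_cv_target must be below the variable CV range (classes must be separable)",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Read a synthetic config from a JSON or YAML file
#'
#' The file's keys mirror the [synthetic_config()] argument names;
#' missing keys take the defaults.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("config file must be .json, .yml or .yaml", call. = FALSE)
  }
  unknown <- setdiff(names(vals), names(formals(synthetic_config)))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(synthetic_config, vals)
}

# substream offsets; kept fixed so streams never collide across purposes
.seed_for <- function(seed, purpose, index = 0L) {
  offset <- switch(purpose, genes = 0L, dataset = 100003L, ct = 499979L)
  as.integer((as.numeric(seed) + offset * (index + 1)) %% 2147483629)
}

#' The shared gene universe of a synthetic study
#'
#' Gene ids, hidden class labels, mean RPKM and CV targets are drawn once
#' from the master seed, so every dataset of a study shares the same
#' genes and planted classes.
#'
#' @param config A [synthetic_config()].
#' @return Data frame `(gene_id, class, mean_rpkm, cv_target)`; `class`
#'   is `"stable"` or `"variable"`, `cv_target` in percent.
#' @export
gene_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_genes
  withr_seed <- .seed_for(config$seed, "genes")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(withr_seed)
  gene_id <- sprintf("gene%05d", seq_len(n))
  n_stable <- round(config$frac_stable * n)
  class <- rep("variable", n)
  if (n_stable > 0) class[sample.int(n, n_stable)] <- "stable"
  mean_rpkm <- 2^stats::runif(n, config$mean_log2_range[1],
                              config$mean_log2_range[2])
  cv_target <- ifelse(class == "stable", config$stable_cv_target,
                      stats::runif(n, config$variable_cv_range[1],
                                   config$variable_cv_range[2]))
  data.frame(gene_id = gene_id, class = class, mean_rpkm = mean_rpkm,
             cv_target = cv_target, stringsAsFactors = FALSE)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate one synthetic RPKM dataset
#'
#' Draws an `n_genes x n_samples` matrix of strictly positive RPKM
#' values from the study's shared gene universe: gene g's values are
#' log-normal with arithmetic mean `mean_rpkm(g)` and log-sd
#' `sqrt(log(1 + (cv_target(g)/100)^2))`. Reproducible given
#' `(seed, dataset_index)`; datasets are independent sample draws.
#'
#' @param config A [synthetic_config()].
#' @param dataset_index Which dataset of the study to generate (1-based).
#' @return An [expression_matrix()] labelled `synth<index>`; the hidden
#'   gene classes are attached as attribute `"planted"` (see
#'   [planted_labels()]).
#' @export
generate_dataset <- function(config, dataset_index = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  dataset_index <- as.integer(dataset_index)
  if (dataset_index < 1) stop("dataset_index must be >= 1", call. = FALSE)
  universe <- gene_universe(config)
  cv <- universe$cv_target / 100
  sigma <- sqrt(log(1 + cv^2))
  mu <- log(universe$mean_rpkm) - sigma^2 / 2
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.seed_for(config$seed, "dataset", dataset_index))
  vals <- matrix(stats::rlnorm(config$n_genes * config$n_samples,
                               meanlog = mu, sdlog = sigma),
                 nrow = config$n_genes,
                 dimnames = list(universe$gene_id,
                                 sprintf("s%03d", seq_len(config$n_samples))))
  out <- expression_matrix(vals,
                           dataset_label = sprintf("synth%d", dataset_index))
  attr(out, "planted") <- universe[, c("gene_id", "class")]
  out
}

#' Hidden planted-class labels of a synthetic dataset
#' @param x A matrix from [generate_dataset()].
#' @return Data frame `(gene_id, class)`, or `NULL` if `x` is not
#'   synthetic.
#' @export
planted_labels <- function(x) attr(x, "planted")

#' Generate a full multi-dataset synthetic study
#'
#' All datasets share the same gene universe (ids, planted classes,
#' per-gene means and CV targets) and differ only by independent sample
#' draws, emulating replicate cohorts profiled on the same gene set.
#'
#' @param config A [synthetic_config()].
#' @return A list of `n_datasets` expression matrices (see
#'   [generate_dataset()]); the shared labels are on attribute
#'   `"planted"` of the list as well as on each matrix.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  mats <- lapply(seq_len(config$n_datasets),
                 function(i) generate_dataset(config, i))
  attr(mats, "planted") <- planted_labels(mats[[1]])
  mats
}

#' Generate a matched qPCR Ct table from RPKM values
#'
#' Applies the log-linear qPCR observation model
#' `Ct(g, s) = ct_intercept - ct_slope * log2(RPKM(g, s)) + e`,
#' `e ~ N(0, ct_noise_sd)`: each doubling of template reduces Ct by
#' `ct_slope` cycles. Requires strictly positive RPKM (the log is
#' undefined at zero).
#'
#' @param matrix Expression matrix of strictly positive RPKM values.
#' @param config A [synthetic_config()] providing the Ct model
#'   parameters and the noise seed.
#' @param genes Gene ids to assay; defaults to all genes of `matrix`.
#' @param dataset_index Substream index for the noise draw; defaults to
#'   the index encoded in the matrix's dataset label, or 1.
#' @return A [ct_table()] for the requested genes.
#' @export
generate_ct_table <- function(matrix, config, genes = rownames(matrix),
                              dataset_index = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing)) {
    stop(sprintf("requested gene(s) absent: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  x <- unclass(matrix)[genes, , drop = FALSE]
  if (any(x <= 0)) {
    stop("all RPKM values must be > 0 (log2 undefined at zero)",
         call. = FALSE)
  }
  if (is.null(dataset_index)) {
    parsed <- suppressWarnings(
      as.integer(sub("^synth", "", dataset_label(matrix))))
    dataset_index <- if (is.na(parsed)) 1L else parsed
  }
  ct <- config$ct_intercept - config$ct_slope * log2(x)
  if (config$ct_noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(.seed_for(config$seed, "ct", dataset_index))
    ct <- ct + matrix(stats::rnorm(length(ct), 0, config$ct_noise_sd),
                      nrow = nrow(ct))
  }
  ct_table(ct)
}

#' Write the hidden labels of a synthetic study as TSV
#'
#' Labels are kept out of the expression files (a sidecar table) so
#' downstream selection code never sees the planted classes.
#'
#' @param labels Data frame `(gene_id, class)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("gene_id", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
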