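#!/usr/bin/env Rscript
# Stage 1: simulate the multi-cohort study.
#
# Generates a 10-dataset synthetic study (2000 genes x 100 samples per
# dataset, 5% planted stable genes at a 10% CV target, variable genes at
# 40-120% CV) and writes each cohort as a TSV expression matrix plus a
# sidecar label table. Later stages read these files, so nothing
# downstream ever sees the planted classes except the final evaluation.
# The matrices are bulky intermediates, so they go under scratch/.

suppressPackageStartupMessages(library(ctrlscreen))

out_dir <- "scratch/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 1)
message(sprintf("simulating %d datasets of %d genes x %d samples (seed %d)",
                cfg$n_datasets, cfg$n_genes, cfg$n_samples, cfg$seed))

study <- generate_study(cfg)
for (m in study) {
  path <- file.path(out_dir, paste0(dataset_label(m), ".tsv"))
  write_matrix(m, path)
}
write_labels(planted_labels(study[[1]]),
             file.path(out_dir, "planted_labels.tsv"))
jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                     auto_unbox = TRUE, digits = NA)

labels <- planted_labels(study[[1]])
message(sprintf("planted %d stable and %d variable genes; wrote %d matrices to %s",
                sum(labels$class == "stable"),
                sum(labels$class == "variable"),
                length(study), out_dir))
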