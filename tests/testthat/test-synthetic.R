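test_that("config validation rejects impossible study conditions", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(n_genes = 0), ">= 1")
  expect_error(synthetic_config(frac_stable = 1.2), "frac_stable")
  expect_error(synthetic_config(ct_noise_sd = -1), "ct_noise_sd")
  expect_error(synthetic_config(stable_cv_target = 50,
                                variable_cv_range = c(40, 120)),
               "separable")
  expect_error(synthetic_config(mean_log2_range = c(12, 2)), "increasing")
  expect_error(synthetic_config(ct_intercept = Inf), "finite")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_genes = 50, n_samples = 20, n_datasets = 3,
                          seed = 77)
  m1 <- generate_dataset(cfg, 2)
  m2 <- generate_dataset(cfg, 2)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])

  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  for (i in 1:3) {
    expect_identical(unclass(s1[[i]])[, ], unclass(s2[[i]])[, ])
  }
  # datasets differ from one another but share the gene universe
  expect_false(identical(unclass(s1[[1]])[, ], unclass(s1[[2]])[, ]))
  expect_identical(rownames(s1[[1]]), rownames(s1[[3]]))
  expect_identical(planted_labels(s1[[1]]), planted_labels(s1[[3]]))

  # adding datasets never perturbs earlier ones
  cfg5 <- synthetic_config(n_genes = 50, n_samples = 20, n_datasets = 5,
                           seed = 77)
  s5 <- generate_study(cfg5)
  expect_identical(unclass(s5[[2]])[, ], unclass(s1[[2]])[, ])
})

test_that("zero-dispersion stable genes have sample CV exactly 0", {
  cfg <- synthetic_config(n_genes = 20, n_samples = 10, n_datasets = 1,
                          frac_stable = 0.5, stable_cv_target = 0,
                          variable_cv_range = c(40, 120), ct_noise_sd = 0,
                          seed = 5)
  mat <- generate_dataset(cfg, 1)
  labels <- planted_labels(mat)
  tab <- stability_table(mat)
  stable_cv <- tab$cv_percent[tab$gene_id %in%
                                labels$gene_id[labels$class == "stable"]]
  expect_equal(stable_cv, rep(0, length(stable_cv)))
})

test_that("empirical CV of planted stable genes matches the target", {
  # CV^2 = exp(sigma_ln^2) - 1 calibration, checked by Monte Carlo
  cfg <- synthetic_config(n_genes = 2000, n_samples = 200, n_datasets = 1,
                          frac_stable = 0.05, stable_cv_target = 10,
                          seed = 1)
  mat <- generate_dataset(cfg, 1)
  labels <- planted_labels(mat)
  tab <- stability_table(mat)
  stable_cv <- tab$cv_percent[tab$gene_id %in%
                                labels$gene_id[labels$class == "stable"]]
  expect_lt(abs(mean(stable_cv) - 10), 2)

  # convergence at large n: within 10% relative
  cfg2 <- synthetic_config(n_genes = 100, n_samples = 1000, n_datasets = 1,
                           frac_stable = 0.5, stable_cv_target = 10,
                           seed = 2)
  mat2 <- generate_dataset(cfg2, 1)
  labels2 <- planted_labels(mat2)
  tab2 <- stability_table(mat2)
  stable_cv2 <- tab2$cv_percent[tab2$gene_id %in%
                                  labels2$gene_id[labels2$class == "stable"]]
  expect_lt(abs(mean(stable_cv2) - 10) / 10, 0.1)
})

test_that("the Ct observation model is log-linear in RPKM", {
  cfg <- synthetic_config(n_genes = 2, n_samples = 3, n_datasets = 1,
                          frac_stable = 0, ct_intercept = 30, ct_slope = 1,
                          ct_noise_sd = 0, seed = 3)
  vals <- matrix(c(1, 2, 4, 8, 16, 32), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  mat <- expression_matrix(vals)
  ct <- generate_ct_table(mat, cfg)
  expect_equal(unname(unclass(ct)["g1", ]), c(30, 29, 28))  # RPKM 1 -> 30
  # doubling RPKM lowers Ct by exactly the slope
  expect_equal(unname(diff(unclass(ct)["g2", ])), c(-1, -1))

  # with noise, tables reproduce under the same seed
  cfgn <- synthetic_config(n_genes = 10, n_samples = 6, n_datasets = 1,
                           ct_noise_sd = 0.2, seed = 4)
  matn <- generate_dataset(cfgn, 1)
  expect_identical(unclass(generate_ct_table(matn, cfgn))[, ],
                   unclass(generate_ct_table(matn, cfgn))[, ])

  # noise-free Spearman between log2 RPKM and Ct is exactly -1
  ct0 <- generate_ct_table(matn, synthetic_config(n_genes = 10,
                                                  n_samples = 6,
                                                  n_datasets = 1,
                                                  ct_noise_sd = 0, seed = 4))
  for (g in rownames(matn)[1:3]) {
    expect_equal(spearman_rho(log2(unclass(matn)[g, ]),
                              unclass(ct0)[g, ]), -1)
  }

  zero <- expression_matrix(matrix(c(0, 1, 2, 3), 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))))
  expect_error(generate_ct_table(zero, cfg), "> 0")
  expect_error(generate_ct_table(mat, cfg, genes = "nope"), "absent")
})

test_that("configs round-trip through JSON files", {
  cfg <- synthetic_config(n_genes = 10, n_samples = 5, n_datasets = 2,
                          seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- read_synthetic_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_identical(unclass(generate_dataset(back, 1))[, ],
                   unclass(generate_dataset(cfg, 1))[, ])
})
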