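test_that("gene_stability matches hand-computed CV and MFC", {
  rec <- gene_stability(c(5, 5, 5, 5))
  expect_equal(rec$cv_percent, 0)
  expect_equal(rec$mfc, 1)

  rec <- gene_stability(c(1, 2, 3))   # mean 2, sample sd 1
  expect_equal(rec$mean_rpkm, 2)
  expect_equal(rec$cv_percent, 50)
  expect_equal(rec$mfc, 3)

  rec <- gene_stability(c(2, 0, 4))
  expect_true(rec$mfc_infinite)
  expect_identical(rec$mfc, Inf)

  expect_error(gene_stability(5), ">= 2 samples")
  expect_error(gene_stability(c(0, 0, 0)), "all-zero")

  # population-denominator switch
  rec_n <- gene_stability(c(1, 2, 3), sd_denom = "n")
  expect_equal(rec_n$cv_percent, 100 * sqrt(2 / 3) / 2)
})

test_that("stability_table ranks by CV with deterministic tie-breaks", {
  vals <- rbind(A = c(3, 3, 3), B = c(1, 2, 3))
  colnames(vals) <- paste0("s", 1:3)
  tab <- stability_table(expression_matrix(vals))
  expect_equal(tab$gene_id[tab$rank == 1], "A")

  # CV ties broken lexicographically by gene id
  vals <- rbind(zz = c(1, 2), aa = c(2, 4))
  colnames(vals) <- c("s1", "s2")
  tab <- stability_table(expression_matrix(vals))
  expect_equal(tab$gene_id, c("aa", "zz"))
})

test_that("stability_table agrees with per-gene brute force on random data", {
  set.seed(21)
  m <- random_expr(50, 20)
  tab <- stability_table(m)
  x <- unclass(m)
  for (g in rownames(x)) {
    row <- tab[tab$gene_id == g, ]
    expect_equal(row$cv_percent, oracle_cv_percent(x[g, ]))
    expect_equal(row$mfc, oracle_mfc(x[g, ]))
    expect_equal(row$mean_rpkm, mean(x[g, ]))
  }
  ord <- order(vapply(rownames(x), function(g) oracle_cv_percent(x[g, ]),
                      numeric(1)), rownames(x))
  expect_identical(tab$gene_id, rownames(x)[ord])
})

test_that("CV, MFC and ranks are invariant under global rescaling", {
  set.seed(22)
  m <- random_expr(30, 10)
  scaled <- expression_matrix(unclass(m)[, ] * 7, dataset_label = "x7")
  t1 <- stability_table(m)
  t2 <- stability_table(scaled)
  expect_identical(t1$gene_id, t2$gene_id)
  expect_equal(t1$cv_percent, t2$cv_percent)
  expect_equal(t1$mfc, t2$mfc)
})

test_that("panel_summary matches a sort-based oracle", {
  set.seed(23)
  m <- random_expr(40, 12)
  tab <- stability_table(m)
  panel <- sample(tab$gene_id, 15)
  ps <- panel_summary(tab, panel)
  sub <- tab[match(panel, tab$gene_id), ]
  expect_equal(ps$median_cv, oracle_median(sub$cv_percent))
  expect_equal(ps$median_mfc, oracle_median(sub$mfc))
  expect_equal(ps$cv_min, min(sub$cv_percent))
  expect_equal(ps$mfc_max, max(sub$mfc))

  one <- panel_summary(tab, panel[1])
  expect_equal(one$median_cv, one$cv_min)
  expect_equal(one$median_cv, one$cv_max)

  expect_error(panel_summary(tab, character(0)), "empty")
  expect_error(panel_summary(tab, "nope"), "absent")
})

test_that("quantile curves match brute-force window enumeration", {
  # constant-CV transcriptome: every curve is flat at that CV
  set.seed(24)
  means <- exp(rnorm(20, 3, 1))
  vals <- outer(means, c(1, 2, 3))  # each gene CV = sd(1,2,3)/2 * 100
  dimnames(vals) <- list(sprintf("g%02d", 1:20), c("s1", "s2", "s3"))
  m <- expression_matrix(vals)
  cc <- quantile_curves(m, window = 5)
  expect_true(all(abs(as.matrix(cc[, -1]) - 50) < 1e-9))

  # 5 genes, window 3: exhaustive check
  set.seed(25)
  m <- random_expr(5, 8)
  cc <- quantile_curves(m, window = 3, levels = c(5, 25, 50, 75))
  ref <- oracle_quantile_curves(unclass(m), 3, c(5, 25, 50, 75))
  expect_equal(unname(as.matrix(cc)), unname(ref))

  # quantile monotonicity across levels, on a bigger random instance
  m <- random_expr(60, 10)
  cc <- quantile_curves(m, window = 20)
  expect_true(all(cc$q5 <= cc$q25 & cc$q25 <= cc$q50 & cc$q50 <= cc$q75))

  expect_error(quantile_curves(m, window = 61), "exceeds")
})

test_that("quantile_position classifies genes against the background", {
  set.seed(26)
  m <- random_expr(30, 6)
  x <- unclass(m)
  x <- rbind(x, flat = rep(mean(x), 6))   # constant gene, CV 0
  m2 <- expression_matrix(x)
  tab <- stability_table(m2)
  cc <- quantile_curves(m2, window = 10)
  expect_equal(suppressWarnings(quantile_position("flat", cc, tab)), 5)

  # classification is invariant under global expression rescaling
  m3 <- expression_matrix(x * 13)
  tab3 <- stability_table(m3)
  cc3 <- quantile_curves(m3, window = 10)
  g <- tab$gene_id[15]
  expect_identical(suppressWarnings(quantile_position(g, cc, tab)),
                   suppressWarnings(quantile_position(g, cc3, tab3)))

  # a gene holding a window's exact median CV sits at the 50% level
  vals <- rbind(g1 = 10 * c(0.9, 1.0, 1.1),   # CV 10%
                g2 = 20 * c(0.8, 1.0, 1.2),   # CV 20%
                g3 = 30 * c(0.7, 1.0, 1.3))   # CV 30%
  colnames(vals) <- paste0("s", 1:3)
  m4 <- expression_matrix(vals)
  tab4 <- stability_table(m4)
  cc4 <- quantile_curves(m4, window = 3)
  expect_equal(quantile_position("g2", cc4, tab4), 50)

  expect_error(quantile_position("absent", cc, tab), "not in table")
})
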