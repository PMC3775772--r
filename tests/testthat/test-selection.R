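test_that("select_candidates applies strict CV/MFC thresholds per stratum", {
  # published leukemia-cohort statistics as transcribed inputs
  cand <- published_panel("candidates")
  conv <- published_panel("conventional")
  tab <- as_stability_table(
    data.frame(gene_id = c(cand$gene, conv$gene),
               mean_rpkm = c(cand$mean, conv$leucegene_mean),
               cv_percent = c(cand$cv, conv$leucegene_cv),
               mfc = c(cand$mfc, conv$leucegene_mfc)),
    dataset_label = "leucegene")

  high <- select_candidates(tab, selection_criteria(), "high")
  expect_equal(high$gene_id[1], "HNRNPK")       # lowest-CV high-stratum gene
  expect_true(all(cand$gene[cand$stratum == "high"] %in% high$gene_id))
  expect_false("TBP" %in% high$gene_id)         # mean 8.1 <= 25: too weak

  mid <- select_candidates(tab, selection_criteria(), "mid")
  expect_false("TBP" %in% mid$gene_id)
  expect_true(all(c("PSMA1", "SF3B2", "EIF4H") %in% mid$gene_id))
  expect_true(all(mid$mean_rpkm > 25 & mid$mean_rpkm <= 100))

  # strict inequality at the boundary
  btab <- as_stability_table(
    data.frame(gene_id = c("edge_cv", "edge_mfc", "ok"),
               mean_rpkm = c(50, 50, 50),
               cv_percent = c(25.0, 20, 20),
               mfc = c(3, 5.0, 3)))
  sel <- select_candidates(btab, selection_criteria(), "mid")
  expect_identical(sel$gene_id, "ok")
})

test_that("high and mid strata partition the candidates above 25 RPKM", {
  set.seed(31)
  m <- random_expr(200, 15)
  tab <- stability_table(m)
  crit <- selection_criteria(cv_max = 40, mfc_max = 10)
  high <- select_candidates(tab, crit, "high")$gene_id
  mid <- select_candidates(tab, crit, "mid")$gene_id
  expect_length(intersect(high, mid), 0)
  all_pass <- tab$gene_id[tab$cv_percent < 40 & is.finite(tab$mfc) &
                            tab$mfc < 10 & tab$mean_rpkm > 25]
  expect_setequal(c(high, mid), all_pass)
})

test_that("cross-dataset score counts CV and MFC passes separately, halved", {
  mk <- function(cv, mfc, label) {
    as_stability_table(
      data.frame(gene_id = c("g1", "g2", "g3"),
                 mean_rpkm = 100, cv_percent = cv, mfc = mfc),
      dataset_label = label)
  }
  # g1 passes both everywhere; g2 passes CV everywhere but MFC only in
  # the first 5 datasets (15/20 checks -> 7.5); g3 fails everything
  tables <- lapply(1:10, function(i) {
    mk(cv = c(10, 10, 60),
       mfc = c(2, if (i <= 5) 2 else 8, 20),
       label = paste0("d", i))
  })
  card <- score_across_datasets(tables, selection_criteria(),
                                c("g1", "g2", "g3"))
  expect_equal(card$score[card$gene_id == "g1"], 10.0)
  expect_equal(card$score[card$gene_id == "g2"], 7.5)
  expect_equal(card$score[card$gene_id == "g3"], 0.0)
  expect_identical(card$gene_id, c("g1", "g2", "g3"))  # rank by score

  # permuting dataset order changes no score
  card2 <- score_across_datasets(tables[c(7, 2, 9, 1, 10, 3, 5, 4, 8, 6)],
                                 selection_criteria(), c("g1", "g2", "g3"))
  expect_equal(card2$score[match(card$gene_id, card2$gene_id)], card$score)

  # tightening any threshold never raises a score
  tight <- score_across_datasets(tables, selection_criteria(cv_max = 5),
                                 c("g1", "g2", "g3"))
  expect_true(all(tight$score[match(card$gene_id, tight$gene_id)] <=
                    card$score))
  tight2 <- score_across_datasets(tables,
                                  selection_criteria(mfc_max = 1.5),
                                  c("g1", "g2", "g3"))
  expect_true(all(tight2$score[match(card$gene_id, tight2$gene_id)] <=
                    card$score))

  # a gene missing from one dataset contributes 0 passes there, warned
  short <- tables
  short[[1]] <- as_stability_table(
    data.frame(gene_id = c("g1", "g2"), mean_rpkm = 100,
               cv_percent = 10, mfc = 2), "d1")
  expect_warning(card3 <- score_across_datasets(short, selection_criteria(),
                                                c("g1", "g2", "g3")),
                 "missing from dataset 'd1'")
  expect_equal(card3$score[card3$gene_id == "g3"], 0.0)
})

test_that("score-card recovery metrics behave on planted labels", {
  card <- structure(
    data.frame(rank = 1:6,
               gene_id = c("s1", "s2", "v1", "s3", "v2", "v3"),
               score = c(10, 10, 9, 8, 2, 0)),
    class = c("score_card", "data.frame"))
  labels <- data.frame(gene_id = c("s1", "s2", "s3", "v1", "v2", "v3"),
                       class = rep(c("stable", "variable"), each = 3))
  rec <- recover_planted(card, labels)        # top_k defaults to 3 stable
  expect_equal(rec$top_k, 3)
  expect_equal(rec$precision, 2 / 3)
  expect_equal(rec$recall, 2 / 3)
  expect_equal(recover_planted(card, labels, top_k = 6)$recall, 1)
  expect_error(recover_planted(card, labels, top_k = 7), "exceeds")
})
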