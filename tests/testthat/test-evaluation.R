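fake_result <- function(markers, p) data.frame(marker = markers, p = p)

test_that("confusion counts match exhaustive enumeration", {
  blocks <- data.frame(marker = paste0("m", 1:8), chrom = "c1",
                       block_id = rep(1:4, each = 2))
  truth <- data.frame(marker = c("m1", "m3"), block_id = c(1L, 2L),
                      effect = c(0.8, 0.2), is_major = c(TRUE, FALSE))
  # significant markers in bins 1 and 3
  res <- fake_result(paste0("m", 1:8),
                     c(1e-9, 1, 1, 1, 1e-9, 1, 1, 1))
  cc <- confusion_counts(res, 0.05, blocks, truth, "all")
  expect_equal(cc[, c("TP", "FP", "TN", "FN")],
               data.frame(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_equal(cc$PO, 0.5)
  expect_equal(cc$FPR, 0.5)

  # nothing significant
  none <- fake_result(paste0("m", 1:8), rep(1, 8))
  c0 <- confusion_counts(none, 0.05, blocks, truth, "all")
  expect_equal(unlist(c0[, c("TP", "FP", "FN", "TN")]),
               c(TP = 0L, FP = 0L, FN = 2L, TN = 2L))
  expect_equal(c0$PO, 0)
  expect_equal(c0$FPR, 0)

  # everything significant
  all_sig <- fake_result(paste0("m", 1:8), rep(1e-9, 8))
  c1 <- confusion_counts(all_sig, 0.05, blocks, truth, "all")
  expect_equal(c1$PO, 1)
  expect_equal(c1$FPR, 1)

  # class-specific positives share the all-QTL negatives
  cm <- confusion_counts(res, 0.05, blocks, truth, "major")
  expect_equal(unlist(cm[, c("TP", "FN", "FP", "TN")]),
               c(TP = 1L, FN = 0L, FP = 1L, TN = 1L))
  cmi <- confusion_counts(res, 0.05, blocks, truth, "minor")
  expect_equal(unlist(cmi[, c("TP", "FN", "FP", "TN")]),
               c(TP = 0L, FN = 1L, FP = 1L, TN = 1L))

  expect_error(confusion_counts(res, 0.05, blocks,
                                data.frame(marker = "zz", is_major = TRUE),
                                "all"),
               "missing from the block partition")
})

test_that("confusion counts agree with a brute-force oracle on random cases", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      B <- sample(5:12, 1)
      blocks <- data.frame(marker = sprintf("m%03d", 1:(2 * B)), chrom = "c1",
                           block_id = rep(seq_len(B), each = 2))
      qb <- sample(B, sample(2:min(4, B - 1), 1))
      truth <- data.frame(marker = sprintf("m%03d", 2 * qb), block_id = qb,
                          effect = stats::runif(length(qb)),
                          is_major = sample(c(TRUE, FALSE), length(qb),
                                            replace = TRUE))
      truth$is_major[which.max(truth$effect)] <- TRUE
      p <- stats::runif(2 * B)
      res <- fake_result(blocks$marker, p)
      for (cl in c("all", "major", "minor")) {
        mine <- confusion_counts(res, 0.3, blocks, truth, cl)
        oracle <- brute_confusion(p, blocks$marker, 0.3, blocks, truth, cl)
        expect_equal(unlist(mine[, c("TP", "FP", "TN", "FN")]), oracle)
        expect_equal(mine$TP + mine$FN, sum(unique(blocks$block_id) %in%
          blocks$block_id[match(switch(cl, all = truth$marker,
                                       major = truth$marker[truth$is_major],
                                       minor = truth$marker[!truth$is_major]),
                                blocks$marker)]))
      }
    }
  })
})

test_that("golden-standard bookkeeping: records, determinism", {
  pan <- small_panel(seed = 83, n_lines = 40, n_markers = 60,
                     length_cM = 80, n_chrom = 2)
  blocks <- single_linkage_blocks(pan$map)
  rec <- run_golden_standard(pan$geno, blocks, h2 = c(0.4, 0.9), n_qtl = 5,
                             thresholds = c("liji", "liberal"), n_iter = 2,
                             missing_rate = 0.3, seed = 5,
                             rf_args = list(n_trees = 20, n_predictors = 6,
                                            max_iter = 1))
  # 4 matrices x 2 h2 x 2 thresholds x 3 classes x 2 iterations
  expect_equal(nrow(rec), 4 * 2 * 2 * 3 * 2)
  expect_setequal(unique(rec$gwas_matrix), c("NImp", "Mean", "MVN-EM", "RF"))
  expect_true(all(rec$sim_matrix == "NoNA"))
  expect_true(all(rec$PO >= 0 & rec$PO <= 1, na.rm = TRUE))
  rec2 <- run_golden_standard(pan$geno, blocks, h2 = c(0.4, 0.9), n_qtl = 5,
                              thresholds = c("liji", "liberal"), n_iter = 2,
                              missing_rate = 0.3, seed = 5,
                              rf_args = list(n_trees = 20, n_predictors = 6,
                                             max_iter = 1))
  expect_identical(rec, rec2)
})

test_that("with no missing data the 4 x 4 ascertainment cells coincide", {
  pan <- small_panel(seed = 89, n_lines = 50, n_markers = 10,
                     length_cM = 90, n_chrom = 7)
  blocks <- single_linkage_blocks(pan$map)
  rec <- run_ascertainment(pan$geno, blocks, h2 = 0.6, n_qtl = 5, n_iter = 2,
                           missing_rate = 0, seed = 4,
                           thresholds = c("liji", "liberal"))
  expect_equal(nrow(rec), 16 * 1 * 2 * 3 * 2)
  for (it in unique(rec$iteration)) {
    for (th in c("liji", "liberal")) {
      s <- rec[rec$iteration == it & rec$threshold == th &
                 rec$qtl_class == "all", ]
      expect_equal(nrow(s), 16L)
      expect_equal(length(unique(s$PO)), 1L)
      expect_equal(length(unique(s$FPR)), 1L)
    }
  }
  # diagonal cells exist for every tag
  expect_setequal(unique(rec$sim_matrix[rec$sim_matrix == rec$gwas_matrix]),
                  c("NImp", "Mean", "MVN-EM", "RF"))
})

test_that("the GBS design uses bins and tags the native missing rate", {
  spec <- wheat_panel_spec(markers_per_chrom = 6, seed = 13, n_lines = 60)
  pan <- generate_panel(spec)
  sparse <- apply_missingness(pan$geno, 0.3, dispersion = 6, seed = 2)
  attr(sparse, "masked") <- NULL
  rec <- run_gbs_experiment(sparse, pan$map, h2 = 0.6, n_qtl = 4, n_iter = 1,
                            seed = 8, subpop = pan$subpop,
                            thresholds = "liberal",
                            rf_args = list(n_trees = 20, n_predictors = 6,
                                           max_iter = 1))
  expect_equal(unique(rec$missing_rate), round(mean(is.na(sparse)), 4))
  expect_equal(nrow(rec), 16 * 3)
  expect_setequal(unique(rec$sim_matrix), c("NImp", "Mean", "MVN-EM", "RF"))
})

test_that("summaries reduce records correctly and ignore row order", {
  rec <- data.frame(sim_matrix = "NoNA", gwas_matrix = rep(c("A", "B"), 2),
                    h2 = 0.5, n_qtl = 5, threshold = "liji",
                    missing_rate = 0.5, qtl_class = "all",
                    iteration = rep(1:2, each = 2),
                    TP = 1, FP = 0, TN = 9, FN = 1,
                    PO = c(0.2, 0.6, 0.4, 0.8),
                    FPR = c(0.0, 0.1, 0.2, 0.3))
  s <- summarize_metrics(rec)
  expect_equal(nrow(s), 2L)
  expect_equal(s$PO_mean[s$gwas_matrix == "A"], 0.3)
  expect_equal(s$PO_mean[s$gwas_matrix == "B"], 0.7)
  expect_equal(s$FPR_mean[s$gwas_matrix == "A"], 0.1)
  expect_equal(s$PO_se[s$gwas_matrix == "A"],
               stats::sd(c(0.2, 0.4)) / sqrt(2))
  shuffled <- summarize_metrics(rec[c(3, 1, 4, 2), ])
  expect_equal(shuffled, s)

  one <- summarize_metrics(rec[1, ])
  expect_equal(one$PO_mean, 0.2)
  expect_equal(one$PO_se, 0)
})

test_that("paired design: positives-class totals match across analysis matrices", {
  rec <- gs_table()
  sub <- rec[rec$threshold == "liji", ]
  # within (iteration, class, h2), TP + FN is the same for all four matrices
  grp <- interaction(sub$iteration, sub$qtl_class, sub$h2, drop = TRUE)
  n_distinct <- tapply(sub$TP + sub$FN, grp, function(v) length(unique(v)))
  expect_true(all(n_distinct == 1))
})

test_that("cutoff nesting makes FPR monotone across thresholds, exactly", {
  rec <- gs_table()
  sub <- rec[rec$qtl_class == "all", ]
  w <- stats::reshape(sub[, c("gwas_matrix", "h2", "iteration", "threshold",
                              "FPR")],
                      idvar = c("gwas_matrix", "h2", "iteration"),
                      timevar = "threshold", direction = "wide")
  expect_true(all(w$FPR.liberal >= w$FPR.liji))
  expect_true(all(w$FPR.liji >= w$FPR.bonferroni))
  # and the same for power
  wp <- stats::reshape(sub[, c("gwas_matrix", "h2", "iteration", "threshold",
                               "PO")],
                       idvar = c("gwas_matrix", "h2", "iteration"),
                       timevar = "threshold", direction = "wide")
  expect_true(all(wp$PO.liberal >= wp$PO.liji))
})

test_that("mean power rises with heritability (allowing one MC inversion)", {
  s <- summarize_metrics(gs_table())
  s <- s[s$threshold == "liji" & s$qtl_class == "all", ]
  for (g in unique(s$gwas_matrix)) {
    sg <- s[s$gwas_matrix == g, ]
    sg <- sg[order(sg$h2), ]
    d <- diff(sg$PO_mean)
    se_pair <- sqrt(sg$PO_se[-1]^2 + sg$PO_se[-nrow(sg)]^2)
    bad <- d < -2 * se_pair
    expect_lte(sum(bad), 1)
  }
})
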