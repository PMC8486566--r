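test_that("auc_with_ci matches the pair-counting point estimate and pROC", {
  perf <- auc_with_ci(c(1, 2, 3, 4, 8, 9, 10, 11, 12, 13),
                      rep(c(FALSE, TRUE), each = 5))
  expect_equal(perf$auc, 1)
  expect_equal(perf$ci_high, 1)
  skip_if_not_installed("pROC")
  set.seed(61)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    s <- round(rnorm(n), 1)
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    mine <- auc_with_ci(s, l)
    ref <- pROC::roc(l, s, quiet = TRUE, direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(mine$se, sqrt(pROC::var(ref, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("threshold metrics come from exact contingency arithmetic", {
  m <- threshold_metrics(c(0.9, 0.4, 0.3, 0.7), c(TRUE, TRUE, FALSE, FALSE),
                         0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.5)
  perfect <- threshold_metrics(c(0.9, 0.8, 0.2, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE), 0.5)
  expect_equal(unlist(perfect[1:3]), c(sensitivity = 1, specificity = 1,
                                       accuracy = 1))
  above <- threshold_metrics(c(0.9, 0.1), c(TRUE, FALSE), 2)
  expect_equal(above$sensitivity, 0)
  expect_equal(above$specificity, 1)
  expect_equal(m$tp + m$fn, 2L)
})

test_that("the QC cascade conserves counts under planted failures", {
  coh <- generate_cohort(small_config(seed = 41L))
  man <- plant_qc_failures(coh$manifest, extraction = 5L, library = 7L,
                           sequencing = 3L, seed = 2L)
  qc <- qc_cascade(man)
  for (co in unique(qc$cohort)) {
    sub <- qc[qc$cohort == co, ]
    expect_equal(sub$entering[1], sum(sub$excluded) + sub$surviving[3])
    expect_equal(sub$surviving[1:2], sub$entering[2:3])
  }
  qc0 <- qc_cascade(coh$manifest)
  expect_true(all(qc0$excluded == 0L))
  bad <- coh$manifest; bad$qc_library[1] <- "maybe"
  expect_error(qc_cascade(bad), "pass or fail")
})

test_that("cohort_table rounds half-up and normalises within breakdowns", {
  expect_equal(round_half_up(26.605), 26.61)
  expect_equal(round_half_up(2.675), 2.68)   # binary-representation tie
  expect_equal(round_half_up(-2.675), -2.68)
  coh <- generate_cohort(small_config(seed = 43L))
  ct <- cohort_table(coh$manifest)
  expect_true(all(abs(ct$groups$male_pct + ct$groups$female_pct - 100) <= 0.02))
  expect_equal(sum(ct$stages$n), 18L)
  expect_lte(abs(sum(ct$stages$pct) - 100), 0.02)
  # single-sample group prints 100.00
  one <- coh$manifest[coh$manifest$cohort == "plasma", ][1, ]
  one$sex <- "M"
  expect_equal(cohort_table(one)$groups$male_pct, 100)
})

test_that("group_mean_test is Welch with a degenerate branch", {
  d <- group_mean_test(rep(2, 5), rep(2, 4))
  expect_equal(d$p, 1)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50, 1)
  res <- group_mean_test(a, b)
  expect_lt(res$p, 0.01)
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$mean_a, mean(a))
  expect_equal(res$sd_b, sd(b))
})

test_that("subgroup_report uses pooled normals and tolerates empty groups", {
  coh <- generate_cohort(small_config(seed = 47L))
  mk <- select_tissue_markers(coh$tissue_pcm, coh$manifest)
  tr <- train_risk_model(coh$plasma_pcm, coh$manifest,
                         mk$region_id[mk$selected], nfolds = 5L)
  feats <- t(coh$plasma_pcm$log2pcm)
  rep_ <- subgroup_report(tr$model, feats, coh$manifest, split = tr$split)
  expect_true(all(c("training", "validation", "NAA", "AA", "adenoma",
                    "stage I", "stage IV", "CRC", "CRC+AA") %in%
                    rep_$report$cohort))
  n_norm <- sum(coh$manifest$cohort == "plasma" &
                  coh$manifest$group == "Normal")
  crc_row <- rep_$report[rep_$report$cohort == "CRC", ]
  expect_equal(crc_row$n_neg, n_norm)
  expect_true(all(rep_$report$ci_low <= rep_$report$auc + 1e-12, na.rm = TRUE))
  expect_true(all(rep_$report$auc <= rep_$report$ci_high + 1e-12, na.rm = TRUE))
  # sample order must not matter
  perm <- sample(nrow(feats))
  rep2 <- subgroup_report(tr$model, feats[perm, ], coh$manifest,
                          split = tr$split)
  expect_equal(rep2$report, rep_$report)
  # an absent subgroup yields an NA row, not an error
  man2 <- coh$manifest[!(coh$manifest$group == "NAA"), ]
  rep3 <- subgroup_report(tr$model, feats, man2, split = tr$split)
  naa <- rep3$report[rep3$report$cohort == "NAA", ]
  expect_equal(naa$n_pos, 0L)
  expect_true(is.na(naa$auc))
})

test_that("a scalar scored as the model reproduces the model's AUC", {
  coh <- generate_cohort(small_config(seed = 53L))
  mk <- select_tissue_markers(coh$tissue_pcm, coh$manifest)
  tr <- train_risk_model(coh$plasma_pcm, coh$manifest,
                         mk$region_id[mk$selected], nfolds = 5L)
  feats <- t(coh$plasma_pcm$log2pcm)
  rep_ <- subgroup_report(tr$model, feats, coh$manifest, split = tr$split)
  sc <- rep_$scores
  sel <- sc$group %in% c("CRC", "Normal")
  row <- scalar_biomarker_eval(sc$score[sel], sc$group[sel] == "CRC")
  expect_equal(row$auc, rep_$report$auc[rep_$report$cohort == "CRC"])
  # direction flip and all-ties behaviour
  flip <- scalar_biomarker_eval(-sc$score[sel], sc$group[sel] == "CRC",
                                direction = "less")
  expect_equal(flip$auc, row$auc)
  const <- scalar_biomarker_eval(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(const$auc, 0.5)
  expect_error(scalar_biomarker_eval(NA_real_, TRUE), "missing")
})
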