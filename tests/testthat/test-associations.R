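test_that("significance tiers follow the class-specific alphas", {
  expect_identical(assign_tier(c(0.005, 0.03, 0.2, NA), "taxon"),
                   c("significant", "approached", "ns", "ns"))
  expect_identical(assign_tier(c(0.03, 0.08, 0.2), "diet"),
                   c("significant", "approached", "ns"))
  expect_identical(assign_tier(0.04, "carg"), "approached")
  expect_identical(assign_tier(0.04, "scfa"), "significant")
})

test_that("windowed correlations recover a planted negative taxon effect", {
  b <- generate_cohort(cohort_config(seed = 202))
  sc <- score_table(b$diaries)
  res <- windowed_severity_correlations(sc, b$fecal, "AX",
                                        feature_class = "otu",
                                        symptoms = "composite")
  cell <- res[res$feature_id == "B_longum_like" & res$window == "w13", ]
  expect_lt(cell$rho, 0)
  expect_true(cell$tier %in% c("significant", "approached"))
  # both windows are distinct cells
  expect_identical(nrow(res[res$feature_id == "B_longum_like", ]), 2L)
})

test_that("a constant feature yields a flagged, ns cell", {
  b <- generate_cohort(cohort_config(seed = 5, n_ax = 8, n_mcc = 8))
  sc <- score_table(b$diaries)
  df <- data.frame(subject = names(b$diaries), flatline = 1)
  res <- profile_correlations(sc, df, "otu", "baseline", "AX",
                              symptoms = "composite",
                              score_fields = "auc_severity")
  expect_identical(res$flag, "zero_variance")
  expect_identical(res$tier, "ns")
  expect_true(is.na(res$rho))
})

test_that("profile correlations drop complete-resolution adaptation scores", {
  sc <- rbind(
    tolerance_scores(make_diary(c(0, 2, 2, 1, 0, 0, 0), subject = "A")),
    tolerance_scores(make_diary(c(0, 2, 2, 1, 1, 1, 1), subject = "B")),
    tolerance_scores(make_diary(c(0, 3, 2, 1, 1, 1, 0), subject = "C")),
    tolerance_scores(make_diary(c(0, 1, 2, 1, 1, 0, 1), subject = "D")),
    tolerance_scores(make_diary(c(0, 4, 3, 2, 2, 1, 1), subject = "E")))
  df <- data.frame(subject = c("A", "B", "C", "D", "E"), f = c(5, 4, 3, 2, 1))
  res <- profile_correlations(sc, df, "otu", "baseline", "AX",
                              symptoms = "composite",
                              score_fields = "auc_adaptation")
  # subject A is complete-resolution: only 4 pairs remain
  expect_identical(res$n, 4L)
})

test_that("permutation-mode cells are bit-for-bit reproducible from the seed", {
  b <- generate_cohort(cohort_config(seed = 77, n_ax = 8, n_mcc = 8))
  sc <- score_table(b$diaries)
  r1 <- windowed_severity_correlations(sc, b$fecal, "AX", "otu",
                                       symptoms = "composite",
                                       pvalue_mode = "permutation",
                                       nperm = 499L, perm_seed = 42L)
  r2 <- windowed_severity_correlations(sc, b$fecal, "AX", "otu",
                                       symptoms = "composite",
                                       pvalue_mode = "permutation",
                                       nperm = 499L, perm_seed = 42L)
  expect_identical(r1, r2)
  # permutation and approx p-values broadly agree on strong signals
  strong <- r1[which.min(r1$p), ]
  approx <- windowed_severity_correlations(sc, b$fecal, "AX", "otu",
                                           symptoms = "composite")
  expect_lt(approx[approx$feature_id == strong$feature_id &
                     approx$window == strong$window, "p"], 0.05)
})

test_that("per-week arm tests find the early AX excess and correct across weeks", {
  b <- generate_cohort(cohort_config(seed = 9))
  tests <- per_week_arm_tests(b$diaries)
  expect_identical(nrow(tests), 30L)  # 5 symptoms x 6 weeks
  comp <- tests[tests$symptom == "composite", ]
  expect_lt(comp$p[comp$week == 2], 0.05)  # peak week separates the arms
  expect_true(all(comp$p_adjusted >= comp$p))
})

test_that("within-arm adaptation tests detect the decline in AX", {
  b <- generate_cohort(cohort_config(seed = 10))
  sc <- score_table(b$diaries)
  ad <- adaptation_tests(sc, "AX")
  comp <- ad[ad$symptom == "composite", ]
  expect_lt(comp$p[comp$contrast == "max_vs_week6"], 0.05)
  expect_lt(comp$p[comp$contrast == "auc_w13_vs_w46"], 0.05)
})
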