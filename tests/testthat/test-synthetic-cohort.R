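test_that("default cohort matches the trial structure", {
  b <- generate_cohort(cohort_config(seed = 1))
  arms <- vapply(b$diaries, `[[`, character(1), "arm")
  expect_identical(sum(arms == "AX"), 15L)
  expect_identical(sum(arms == "MCC"), 16L)
  doses <- vapply(b$diaries, `[[`, integer(1), "dose_g_per_day")
  sexes <- vapply(b$diaries, `[[`, character(1), "sex")
  expect_true(all(doses[sexes == "F"] == 25L))
  expect_true(all(doses[sexes == "M"] == 35L))
  expect_identical(sum(sexes[arms == "AX"] == "F"), 10L)
  expect_identical(sum(sexes[arms == "MCC"] == "F"), 11L)
})

test_that("generation is byte-identical under a fixed seed", {
  b1 <- generate_cohort(cohort_config(seed = 123))
  b2 <- generate_cohort(cohort_config(seed = 123))
  expect_identical(b1, b2)
  b3 <- generate_cohort(cohort_config(seed = 124))
  expect_false(identical(b1$fecal$values, b3$fecal$values))
})

test_that("generated ratings are valid ordinals and composites bounded", {
  for (s in 1:5) {
    b <- generate_cohort(cohort_config(seed = s))
    for (d in b$diaries) {
      expect_true(all(d$ratings %in% 0:4))
      comp <- composite_rating(d$ratings["flatulence", ],
                               d$ratings["bloating", ],
                               d$ratings["stomachache", ])
      expect_true(all(comp >= 0 & comp <= 12))
    }
  }
})

test_that("abundance rows lie on the simplex to 1e-9", {
  b <- generate_cohort(cohort_config(seed = 2))
  expect_true(all(abs(rowSums(b$fecal$values) - 1) < 1e-9))
  expect_true(all(abs(rowSums(b$exvivo$values) - 1) < 1e-9))
  expect_true(all(b$fecal$values >= 0))
})

test_that("taxon universe spans >= 4 phyla with a 6-member planted CARG", {
  b <- generate_cohort(cohort_config(seed = 2))
  phyla <- unique(vapply(strsplit(b$taxonomy, ";"), `[`, character(1), 1))
  expect_gte(length(phyla), 4L)
  expect_identical(sum(b$carg_map == "CARG1_like"), 6L)
  expect_length(unique(b$carg_map), 7L)
  expect_length(b$whitelist, 15L)
  expect_true("B_longum_like" %in% names(b$carg_map)[b$carg_map == "CARG1_like"])
})

test_that("metabolite panels respect their invariants", {
  b <- generate_cohort(cohort_config(seed = 4))
  m <- b$metabolites
  expect_true(all(m$ph > 0 & m$ph < 14))
  expect_true(all(m$total + 1e-9 >= pmax(m$acetate, m$propionate, m$butyrate)))
  expect_true(all(m[, c("acetate", "propionate", "butyrate")] >= 0))
})

test_that("ground truth lists the planted effects and empties under null", {
  gt <- ground_truth(cohort_config())
  expect_true(any(gt$feature_id == "B_longum_like" &
                    gt$score_name == "composite.auc_adaptation" &
                    gt$window == "baseline" & gt$sign > 0))
  expect_true(any(gt$feature_id == "meat:wgrain" &
                    gt$score_name == "composite.auc_severity" & gt$sign > 0))
  expect_identical(nrow(ground_truth(cohort_config(null_mode = TRUE))), 0L)
})

test_that("infeasible effect targets and degenerate arms are rejected", {
  expect_error(cohort_config(tolerance_effect_rho = 1), "infeasible")
  expect_error(cohort_config(n_ax = 3), ">= 4")
  expect_error(cohort_config(acetate_link = Inf), "finite")
})

test_that("severity wiring is monotone: more planted taxon, milder symptoms", {
  # across replicate cohorts the z -> severity rank correlation is negative
  rs <- vapply(1:30, function(s) {
    b <- generate_cohort(cohort_config(seed = s))
    lat <- b$latents[b$latents$arm == "AX", ]
    sc <- score_table(b$diaries)
    sc <- sc[sc$symptom == "composite" & sc$arm == "AX", ]
    cor(lat$z, sc$auc_severity[match(lat$subject, sc$subject)],
        method = "spearman")
  }, numeric(1))
  expect_lt(mean(rs), -0.2)
  expect_gt(mean(rs < 0), 0.9)
})

test_that("null mode severs the planted links", {
  rs <- vapply(1:30, function(s) {
    b <- generate_cohort(cohort_config(seed = s, null_mode = TRUE))
    lat <- b$latents[b$latents$arm == "AX", ]
    sc <- score_table(b$diaries)
    sc <- sc[sc$symptom == "composite" & sc$arm == "AX", ]
    cor(lat$z, sc$auc_severity[match(lat$subject, sc$subject)],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
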