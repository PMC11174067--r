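test_that("diary writer/reader round-trip is the identity", {
  d1 <- make_diary(c(0, 1, 2, 2, 1, 1, 0))
  d2 <- make_diary(c(1, 1, 1, 1, 1, 1, 1), subject = "S2", arm = "MCC",
                   sex = "M")
  path <- withr::local_tempfile(fileext = ".csv")
  write_symptom_diaries(list(d1, d2), path)
  back <- read_symptom_diaries(path)
  expect_length(back, 2L)
  expect_identical(back$S1$ratings, d1$ratings)
  expect_identical(back$S2$ratings, d2$ratings)
  expect_identical(back$S2$arm, "MCC")
  expect_identical(back$S2$dose_g_per_day, 35L)
  expect_identical(back$S1$dose_g_per_day, 25L)
})

test_that("diary validation rejects bad rows with a useful message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,arm,sex,week,symptom,rating",
               "S1,AX,F,0,flatulence,5"), path)
  expect_error(read_symptom_diaries(path), "outside \\[0,4\\].*S1.*week 0",
               class = "fibertol_validation_error")
  writeLines(c("subject,arm,sex,week,symptom,rating",
               "S1,AX,F,0,flatulence,2",
               "S1,AX,F,0,flatulence,2"), path)
  expect_error(read_symptom_diaries(path), "duplicate",
               class = "fibertol_validation_error")
  writeLines(c("subject,arm,sex,week,symptom,rating",
               "S1,PLACEBO,F,0,flatulence,2"), path)
  expect_error(read_symptom_diaries(path), "unknown arm",
               class = "fibertol_validation_error")
})

test_that("weeks absent from the file become declared-missing cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- expand.grid(week = c(0:3, 5:6),
                      symptom = c("overall", "flatulence", "bloating",
                                  "stomachache"))
  writeLines(c("subject,arm,sex,week,symptom,rating",
               sprintf("S1,AX,F,%d,%s,1", rows$week, rows$symptom)), path)
  d <- read_symptom_diaries(path)$S1
  expect_true(all(is.na(d$ratings[, "week4"])))
  expect_false(anyNA(d$ratings[, -5]))
})

test_that("abundance reader auto-detects percent encoding and renormalizes", {
  base <- data.frame(sample_id = c("a", "b"), subject = c("S1", "S2"),
                     timepoint = "baseline")
  pct <- cbind(base, OTU1 = c(60, 20), OTU2 = c(40, 80))
  frac <- cbind(base, OTU1 = c(0.6, 0.2), OTU2 = c(0.4, 0.8))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(pct, p1, row.names = FALSE, quote = FALSE)
  write.csv(frac, p2, row.names = FALSE, quote = FALSE)
  t1 <- read_abundance_table(p1)
  t2 <- read_abundance_table(p2)
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
  expect_equal(unname(rowSums(t1$values)), c(1, 1), tolerance = 1e-12)
})

test_that("CARG membership must be a partition", {
  vals <- matrix(c(0.5, 0.5), 1, 2,
                 dimnames = list(NULL, c("OTU1", "OTU2")))
  expect_error(
    abundance_table(vals, "s1", "S1", "baseline",
                    carg_map = setNames(c("C1", "C2", "C1"),
                                        c("OTU1", "OTU2", "OTU1"))),
    "partition", class = "fibertol_validation_error")
})

test_that("negative abundances and off-simplex rows are rejected", {
  vals <- matrix(c(-0.1, 1.1), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(abundance_table(vals, "s1", "S1", "baseline"), "negative")
  vals2 <- matrix(c(0.5, 0.4), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(abundance_table(vals2, "s1", "S1", "baseline"), "sum to 1")
})

test_that("results writer round-trips the tidy table and handles empties", {
  dir <- withr::local_tempdir()
  res <- data.frame(feature_id = c("f1", "f1", "f2"),
                    feature_class = "otu",
                    score_name = "composite.auc_severity",
                    window = c("w13", "w46", "w13"), arm = "AX",
                    n = 15L, rho = c(-0.5, -0.25, 0.125), p = c(0.01, 0.2, 0.7),
                    p_adjusted = c(0.01, 0.2, 0.7),
                    tier = c("significant", "ns", "ns"), flag = "ok",
                    stringsAsFactors = FALSE)
  scores <- data.frame(subject = "S1", symptom = "composite")
  write_results(res, scores, dir)
  back <- read_results(dir)
  expect_equal(back[order(back$feature_id, back$window), ],
               res[order(res$feature_id, res$window), ],
               ignore_attr = TRUE)
  # matrix file: one column per (score, window, arm) cell
  mat <- read.csv(file.path(dir, "associations_otu_rho_matrix.csv"),
                  check.names = FALSE)
  expect_setequal(names(mat)[-1],
                  c("composite.auc_severity.w13.AX",
                    "composite.auc_severity.w46.AX"))
  # empty results give a header-only long file
  dir2 <- withr::local_tempdir()
  write_results(res[0, ], scores, dir2)
  expect_identical(nrow(read_results(dir2)), 0L)
})
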