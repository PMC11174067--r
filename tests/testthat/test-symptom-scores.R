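test_that("composite rating sums the three component symptoms", {
  expect_identical(composite_rating(0, 0, 0), 0)
  expect_identical(composite_rating(4, 4, 4), 12)
  expect_identical(composite_rating(2, 1, 0), 3)
  expect_error(composite_rating(5, 0, 0), "0-4",
               class = "fibertol_validation_error")
  expect_error(composite_rating(1.5, 0, 0), "0-4")
})

test_that("trapezoid rule matches hand computations", {
  expect_equal(trapezoid_auc(c(4, 4, 4), 1:3), 8)
  expect_equal(trapezoid_auc(c(0, 1, 2, 3), 0:3), 4.5)  # 0.5 + 1.5 + 2.5
  expect_equal(trapezoid_auc(rep(3, 7), 0:6), 18)
  expect_error(trapezoid_auc(1, 1), "at least 2")
  expect_error(trapezoid_auc(c(1, 2), c(1, 3)), "unit-spaced")
})

test_that("MAX severity subtracts baseline from the weeks 1-5 peak", {
  expect_equal(max_severity(c(1, 2, 3, 2, 1, 1, 0)), 2)
  expect_equal(max_severity(rep(1, 7)), 0)
  expect_equal(max_severity(c(0, 0, 0, 0, 0, 0, 0)), 0)
  # week 6 is not consulted, even when it is the global maximum
  expect_equal(max_severity(c(0, 1, 1, 1, 1, 1, 4)), 1)
  expect_error(max_severity(c(1, NA, NA, NA, NA, NA, 2)), "undefined")
})

test_that("MAX adaptation subtracts week 6 from the weeks 1-5 peak", {
  # trajectory in the style of the worst-tolerance subject: peak rise 10,
  # week-6 rise 6 => adaptation 4
  tr <- c(0, 6, 10, 8, 7, 6, 6)
  expect_equal(max_adaptation(tr), 4)
  expect_equal(max_severity(tr), 10)
  expect_equal(max_adaptation(rep(2, 7)), 0)
  expect_equal(max_adaptation(c(0, 3, 2, 1, 1, 1, 0)), 3)  # full recovery
  expect_error(max_adaptation(c(0, 1, 1, 1, 1, 1, NA)), "week 6")
})

test_that("AUC severity: incremental nulls at 0, raw matches constant rule", {
  expect_equal(auc_severity(rep(3, 7)), 0)
  expect_equal(auc_severity(c(0, 2, 2, 2, 2, 2, 2)), 11)  # 1+2+2+2+2+2
  expect_equal(auc_severity(rep(4, 7), mode = "raw"), 24)
  # translation invariance (incremental) / 6c shift (raw)
  tr <- c(0, 1, 3, 2, 1, 1, 0)
  expect_equal(auc_severity(tr + 1), auc_severity(tr))
  expect_equal(auc_severity(tr + 1, mode = "raw"),
               auc_severity(tr, mode = "raw") + 6)
})

test_that("AUC adaptation is the w13/w46 segment ratio with flags", {
  expect_equal(auc_adaptation(rep(2, 7))$auc_adaptation, 1)
  r <- auc_adaptation(c(0, 4, 4, 4, 2, 2, 2))
  expect_equal(r$auc_w13, 8)
  expect_equal(r$auc_w46, 4)
  expect_equal(r$auc_adaptation, 2)
  z <- auc_adaptation(c(0, 0, 0, 0, 0, 0, 0))
  expect_equal(z$auc_adaptation, 1)
  expect_true(z$zero_symptom)
  cr <- auc_adaptation(c(0, 2, 2, 1, 0, 0, 0))
  expect_true(cr$complete_resolution)
  expect_identical(cr$auc_adaptation, Inf)
  # scale invariance: multiplying ratings by k > 0 leaves the ratio alone
  tr <- c(1, 3, 4, 3, 2, 2, 1)
  expect_equal(auc_adaptation(tr * 2.5)$auc_adaptation,
               auc_adaptation(tr)$auc_adaptation)
})

test_that("score properties hold over random trajectories", {
  set.seed(421)
  for (i in 1:200) {
    tr <- random_trajectory()
    ms <- max_severity(tr)
    expect_true(all(ms >= tr[2:6] - tr[1]))
    expect_equal(auc_severity(tr + 2), auc_severity(tr))
    ad <- auc_adaptation(tr)
    if (!ad$zero_symptom && !ad$complete_resolution) {
      expect_gte(ad$auc_adaptation, 0)
      expect_equal(auc_adaptation(tr * 3)$auc_adaptation, ad$auc_adaptation)
    }
  }
})

test_that("scaled magnitude is an affine map with guarded sd", {
  expect_equal(scaled_magnitude(24, 24, 3), 0)
  expect_equal(scaled_magnitude(1, 1, 0.5), 0)
  expect_equal(scaled_magnitude(30, 24, 3), 2 * scaled_magnitude(27, 24, 3))
  expect_error(scaled_magnitude(1, 0, 0), "sd")
})

test_that("composite scores come from the summed trajectory, not summed scores", {
  d <- make_diary(c(0, 0, 0, 0, 0, 0, 0),
                  overrides = list(flatulence  = c(0, 3, 0, 0, 0, 0, 0),
                                   bloating    = c(0, 0, 3, 0, 0, 0, 0),
                                   stomachache = c(0, 0, 0, 3, 0, 0, 0)))
  sc <- tolerance_scores(d)
  comp <- sc[sc$symptom == "composite", ]
  # per-symptom maxima do not co-occur: composite MAX is 3, not 9
  expect_equal(comp$max_severity, 3)
  per_sym <- sc[sc$symptom %in% c("flatulence", "bloating", "stomachache"), ]
  expect_equal(sum(per_sym$max_severity), 9)
})

test_that("missing-week policies behave as declared", {
  tr <- c(0, 1, NA, 3, 2, 1, 0)
  expect_true(is.na(max_severity(tr, missing = "strict")))
  expect_equal(max_severity(tr, missing = "interpolate"), 3)
  expect_equal(auc_severity(tr, missing = "interpolate"),
               auc_severity(c(0, 1, 2, 3, 2, 1, 0)))
  # boundary weeks cannot be interpolated
  expect_true(is.na(auc_severity(c(NA, 1, 1, 1, 1, 1, 0),
                                 missing = "interpolate")))
})

test_that("segment severity applies the configured AUC mode", {
  d <- make_diary(c(1, 3, 3, 3, 2, 2, 2))
  inc <- tolerance_scores(d, auc_mode = "incremental")
  raw <- tolerance_scores(d, auc_mode = "raw")
  i1 <- inc[inc$symptom == "overall", ]
  r1 <- raw[raw$symptom == "overall", ]
  expect_equal(segment_severity(i1, "w13"), 6 - 2 * 1)
  expect_equal(segment_severity(r1, "w13"), 6)
  expect_equal(segment_severity(r1, "w46"), 4)
})
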