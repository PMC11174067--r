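#' Composite symptom rating
#'
#' Weekly sum of the flatulence, bloating and stomachache ratings, giving a
#' 0-12 composite scale (higher = more severe).  The "overall" diary rating
#' is not part of the composite.
#'
#' @param flatulence,bloating,stomachache Integer ratings in 0-4 (vectors
#'   allowed; `NA` propagates).
#' @return Integer composite rating(s) in 0-12.
#' @export
composite_rating <- function(flatulence, bloating, stomachache) {
  for (v in list(flatulence, bloating, stomachache)) {
    bad <- !is.na(v) & (v != round(v) | v < 0 | v > 4)
    if (any(bad)) stop_validation("rating outside the 0-4 ordinal scale")
  }
  flatulence + bloating + stomachache
}

#' Trapezoidal area under a weekly trajectory
#'
#' Standard trapezoidal rule over unit-spaced week coordinates; a constant
#' level c over k intervals integrates to c*k.
#'
#' @param values Numeric vector of ratings.
#' @param week_coords Strictly increasing, unit-spaced integer weeks aligned
#'   with `values`.
#' @return Area in point-weeks.
#' @export
trapezoid_auc <- function(values, week_coords) {
  if (length(values) < 2L) stop_validation("AUC needs at least 2 points")
  if (length(values) != length(week_coords)) {
    stop_validation("values and week_coords lengths differ")
  }
  d <- diff(week_coords)
  if (any(d != 1)) stop_validation("week_coords must be unit-spaced increasing")
  sum((values[-1L] + values[-length(values)]) / 2)
}

weeks_of <- function(trajectory, idx) trajectory[idx + 1L]  # week w -> position w+1

# Apply the missing-week policy; returns the (possibly interpolated)
# trajectory, or NULL if required weeks cannot be filled.
resolve_missing <- function(trajectory, required, policy = c("strict", "interpolate")) {
  policy <- match.arg(policy)
  if (!anyNA(trajectory[required + 1L])) return(trajectory)
  if (policy == "strict") return(NULL)
  obs <- which(!is.na(trajectory))
  if (length(obs) < 2L) return(NULL)
  filled <- trajectory
  inner <- setdiff(which(is.na(trajectory)), c(seq_len(min(obs) - 1L),
                                               seq_len(7L)[seq_len(7L) > max(obs)]))
  if (length(inner)) {
    filled[inner] <- stats::approx(obs, trajectory[obs], xout = inner)$y
  }
  if (anyNA(filled[required + 1L])) return(NULL)  # boundary weeks cannot interpolate
  filled
}

#' MAX severity score
#'
#' Highest rating reported during intervention weeks 1-5 minus the baseline
#' (week 0) rating.  Week 6 is deliberately not consulted; it belongs to the
#' adaptation score.
#'
#' @param trajectory 7-vector of ratings, weeks 0-6 (week 6 may be `NA`).
#' @param missing Missing-week policy: `"strict"` (any required week missing
#'   makes the score undefined, returned as `NA`) or `"interpolate"`.
#' @return Integer score; higher = more intense symptoms.
#' @export
max_severity <- function(trajectory, missing = "strict") {
  if (all(is.na(weeks_of(trajectory, 1:5)))) {
    stop_validation("all of weeks 1-5 missing: MAX severity undefined")
  }
  tr <- resolve_missing(trajectory, required = 0:5, policy = missing)
  if (is.null(tr)) return(NA_real_)
  max(weeks_of(tr, 1:5)) - weeks_of(tr, 0)
}

#' MAX adaptation score
#'
#' Highest rating during weeks 1-5 minus the week-6 rating; higher scores
#' mean a larger end-of-trial reduction in symptom intensity.
#'
#' @inheritParams max_severity
#' @return Integer score.
#' @export
max_adaptation <- function(trajectory, missing = "strict") {
  if (is.na(weeks_of(trajectory, 6)) && missing == "strict") {
    stop_validation("week 6 missing: MAX adaptation undefined")
  }
  tr <- resolve_missing(trajectory, required = 1:6, policy = missing)
  if (is.null(tr)) return(NA_real_)
  max(weeks_of(tr, 1:5)) - weeks_of(tr, 6)
}

#' AUC severity score
#'
#' Trapezoidal area of the weekly trajectory over weeks 0-6.  In the default
#' `"incremental"` mode the baseline rating is subtracted from every week
#' first, so a subject whose symptoms never move scores exactly 0.  In
#' `"raw"` mode the unadjusted ratings are integrated (a constant composite
#' of 4 scores 24), the convention behind magnitude scaling with offset 24.
#'
#' @inheritParams max_severity
#' @param mode `"incremental"` (default) or `"raw"`.
#' @return Score in point-weeks; `NA` if the missing policy leaves required
#'   weeks unresolved.
#' @export
auc_severity <- function(trajectory, mode = c("incremental", "raw"),
                         missing = "strict") {
  mode <- match.arg(mode)
  tr <- resolve_missing(trajectory, required = 0:6, policy = missing)
  if (is.null(tr)) return(NA_real_)
  v <- if (mode == "incremental") tr - weeks_of(tr, 0) else tr
  trapezoid_auc(v, WEEKS)
}

#' AUC adaptation score
#'
#' Ratio of the weeks-1-3 trapezoidal AUC to the weeks-4-6 AUC of the raw
#' ratings.  Values above 1 mean symptoms declined over the trial
#' (adaptation); any constant trajectory gives exactly 1.  Two degenerate
#' cases are flagged: a fully asymptomatic subject (both segment AUCs zero)
#' returns 1 with `zero_symptom = TRUE`, and complete late resolution
#' (weeks 4-6 AUC zero but early AUC positive) returns `Inf` with
#' `complete_resolution = TRUE`; flagged values are excluded from
#' correlations by default.
#'
#' @inheritParams max_severity
#' @return List: `auc_adaptation`, `auc_w13`, `auc_w46`, `zero_symptom`,
#'   `complete_resolution`.
#' @export
auc_adaptation <- function(trajectory, missing = "strict") {
  tr <- resolve_missing(trajectory, required = 1:6, policy = missing)
  if (is.null(tr)) {
    return(list(auc_adaptation = NA_real_, auc_w13 = NA_real_,
                auc_w46 = NA_real_, zero_symptom = FALSE,
                complete_resolution = FALSE))
  }
  a13 <- trapezoid_auc(weeks_of(tr, 1:3), 1:3)
  a46 <- trapezoid_auc(weeks_of(tr, 4:6), 4:6)
  if (a46 == 0 && a13 == 0) {
    return(list(auc_adaptation = 1, auc_w13 = a13, auc_w46 = a46,
                zero_symptom = TRUE, complete_resolution = FALSE))
  }
  if (a46 == 0) {
    return(list(auc_adaptation = Inf, auc_w13 = a13, auc_w46 = a46,
                zero_symptom = FALSE, complete_resolution = TRUE))
  }
  list(auc_adaptation = a13 / a46, auc_w13 = a13, auc_w46 = a46,
       zero_symptom = FALSE, complete_resolution = FALSE)
}

#' Scaled magnitude of a tolerance score
#'
#' Affine scaling `(score - offset) / sd` used to draw individualized
#' severity/adaptation circles: offset 24 for raw AUC severity (the raw AUC
#' of a constant maximal composite), 1 for AUC adaptation (the no-change
#' null), 0 for MAX scores; `sd` is the across-subject standard deviation
#' within the arm.  Sign is preserved so the direction of change is
#' recoverable.
#'
#' @param score Numeric score(s).
#' @param offset Null-value offset for the score type.
#' @param sd Positive standard deviation across the arm's subjects.
#' @return Scaled value(s).
#' @export
scaled_magnitude <- function(score, offset, sd) {
  if (!is.finite(sd) || sd <= 0) stop_validation("sd must be > 0")
  (score - offset) / sd
}

#' All tolerance scores for one subject
#'
#' Computes MAX/AUC severity and adaptation scores plus segment AUCs for the
#' four diary symptoms and the composite (the composite trajectory is summed
#' week-by-week first, then scored; per-symptom scores are never added).
#' Also derives the "reverted to baseline" flag: symptoms are considered to
#' have reverted when MAX severity and MAX adaptation differ by at most one
#' point.
#'
#' @param diary A [symptom_diary()].
#' @param auc_mode AUC severity mode, `"incremental"` or `"raw"`.
#' @param missing Missing-week policy (`"strict"` or `"interpolate"`).
#' @return Data frame, one row per symptom (including `"composite"`).
#' @export
tolerance_scores <- function(diary, auc_mode = "incremental",
                             missing = "strict") {
  traj <- rbind(diary$ratings,
                composite = composite_rating(diary$ratings["flatulence", ],
                                             diary$ratings["bloating", ],
                                             diary$ratings["stomachache", ]))
  rows <- lapply(SCORE_SYMPTOMS, function(sym) {
    tr <- traj[sym, ]
    ms <- tryCatch(max_severity(tr, missing), fibertol_validation_error =
                     function(e) NA_real_)
    ma <- tryCatch(max_adaptation(tr, missing), fibertol_validation_error =
                     function(e) NA_real_)
    ad <- auc_adaptation(tr, missing)
    data.frame(subject = diary$subject_id, arm = diary$arm, sex = diary$sex,
               symptom = sym,
               baseline = unname(tr[1L]),
               max_severity = ms,
               auc_severity = auc_severity(tr, auc_mode, missing),
               max_adaptation = ma,
               auc_adaptation = ad$auc_adaptation,
               auc_w13 = ad$auc_w13, auc_w46 = ad$auc_w46,
               zero_symptom = ad$zero_symptom,
               complete_resolution = ad$complete_resolution,
               reverted = if (is.na(ms) || is.na(ma)) NA else abs(ms - ma) <= 1,
               auc_mode = auc_mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tolerance-score table for a cohort
#'
#' @param diaries List of [symptom_diary()] objects.
#' @inheritParams tolerance_scores
#' @return Data frame, one row per subject x symptom.
#' @export
score_table <- function(diaries, auc_mode = "incremental", missing = "strict") {
  do.call(rbind, c(lapply(diaries, tolerance_scores, auc_mode = auc_mode,
                          missing = missing), make.row.names = FALSE))
}

#' Windowed segment severity score
#'
#' Severity over one half of the trial: the trapezoidal AUC of ratings at
#' weeks 1-3 or weeks 4-6.  In `"incremental"` mode the baseline rating is
#' subtracted first (each segment spans 2 week-intervals, so the null is 0);
#' `"raw"` integrates the ratings as reported.  These are the score values
#' paired with week-1 and week-6 fecal samples in windowed correlations.
#'
#' @param scores Row(s) of a [score_table()].
#' @param window `"w13"` or `"w46"`.
#' @return Numeric vector of segment severities.
#' @export
segment_severity <- function(scores, window = c("w13", "w46")) {
  window <- match.arg(window)
  seg <- if (window == "w13") scores$auc_w13 else scores$auc_w46
  mode <- unique(scores$auc_mode)
  if (length(mode) > 1L) stop_validation("mixed auc_mode in score rows")
  if (identical(mode, "incremental")) seg - 2 * scores$baseline else seg
}
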