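#' Construct a symptom diary
#'
#' A symptom diary holds one subject's weekly ordinal symptom ratings for a
#' six-week fiber supplementation trial: four symptoms (overall, flatulence,
#' bloating, stomachache), each rated 0 (none) to 4 (severe) at baseline
#' (week 0) and at the end of each intervention week (weeks 1-6).
#'
#' @param subject_id Subject identifier (opaque string).
#' @param arm Treatment arm, `"AX"` (fermentable arabinoxylan) or `"MCC"`
#'   (non-fermentable microcrystalline cellulose control).
#' @param sex `"F"` or `"M"`; fixes the supplement dose (25 g/day female,
#'   35 g/day male).
#' @param ratings Numeric matrix, 4 rows named after the symptoms and 7
#'   columns for weeks 0-6.  `NA` marks a declared-missing rating.
#' @return An object of class `symptom_diary`.
#' @export
symptom_diary <- function(subject_id, arm, sex, ratings) {
  arm <- match.arg(arm, c("AX", "MCC"))
  sex <- match.arg(sex, c("F", "M"))
  ratings <- as.matrix(ratings)
  if (!identical(dim(ratings), c(4L, 7L))) {
    stop_validation("subject ", subject_id,
                    ": ratings must be a 4 x 7 (symptom x week) matrix")
  }
  rownames(ratings) <- DIARY_SYMPTOMS
  colnames(ratings) <- paste0("week", WEEKS)
  ok <- is.na(ratings) | (ratings == round(ratings) & ratings >= 0 & ratings <= 4)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_validation("subject ", subject_id, ": rating out of [0,4] at symptom ",
                    DIARY_SYMPTOMS[bad[1L]], ", week ", bad[2L] - 1L)
  }
  structure(list(subject_id = as.character(subject_id), arm = arm, sex = sex,
                 dose_g_per_day = if (sex == "F") 25L else 35L,
                 ratings = ratings),
            class = "symptom_diary")
}

#' @export
print.symptom_diary <- function(x, ...) {
  cat(sprintf("<symptom_diary> subject %s | arm %s | %s, %d g/day\n",
              x$subject_id, x$arm, x$sex, x$dose_g_per_day))
  print(x$ratings)
  invisible(x)
}

#' Read weekly symptom diaries from a long-format delimited file
#'
#' Expects columns `subject`, `arm`, `sex`, `week`, `symptom`, `rating`
#' (names remappable through `schema`); comma or tab delimited, auto-detected.
#' Weeks absent from the file become declared-missing cells; ratings are
#' validated against the 0-4 ordinal scale and duplicates are rejected.
#'
#' @param path Path to the delimited file.
#' @param schema Optional named list remapping the expected column names,
#'   e.g. `list(subject = "participant_id")`.
#' @return List of [symptom_diary()] objects, one per subject.
#' @export
read_symptom_diaries <- function(path, schema = list()) {
  df <- read_table_auto(path, colClasses = "character")
  cols <- c(subject = "subject", arm = "arm", sex = "sex", week = "week",
            symptom = "symptom", rating = "rating")
  for (nm in names(schema)) cols[[nm]] <- schema[[nm]]
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols)) {
    stop_validation("diary file missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  week <- suppressWarnings(as.numeric(df[[cols["week"]]]))
  rating <- suppressWarnings(as.numeric(df[[cols["rating"]]]))
  if (anyNA(week)) stop_validation("non-numeric week value")
  bad_rating <- is.na(rating) & nzchar(trimws(df[[cols["rating"]]]))
  if (any(bad_rating)) stop_validation("non-numeric rating value")
  df <- data.frame(subject = df[[cols["subject"]]],
                   arm = df[[cols["arm"]]],
                   sex = df[[cols["sex"]]],
                   week = week,
                   symptom = df[[cols["symptom"]]],
                   rating = rating,
                   stringsAsFactors = FALSE)
  if (!all(df$arm %in% c("AX", "MCC"))) {
    stop_validation("unknown arm label(s): ",
                    paste(unique(setdiff(df$arm, c("AX", "MCC"))), collapse = ", "))
  }
  if (!all(df$week %in% WEEKS)) {
    stop_validation("week values must lie in 0..6")
  }
  if (!all(df$symptom %in% DIARY_SYMPTOMS)) {
    stop_validation("unknown symptom label(s): ",
                    paste(unique(setdiff(df$symptom, DIARY_SYMPTOMS)), collapse = ", "))
  }
  bad <- !is.na(df$rating) &
    (df$rating != round(df$rating) | df$rating < 0 | df$rating > 4)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_validation("rating ", df$rating[i], " outside [0,4] for subject ",
                    df$subject[i], ", week ", df$week[i], ", symptom ",
                    df$symptom[i])
  }
  key <- paste(df$subject, df$week, df$symptom)
  if (anyDuplicated(key)) {
    stop_validation("duplicate (subject, week, symptom) row: ",
                    key[which(duplicated(key))[1L]])
  }
  lapply(split(df, df$subject), function(d) {
    m <- matrix(NA_real_, 4L, 7L, dimnames = list(DIARY_SYMPTOMS, paste0("week", WEEKS)))
    m[cbind(match(d$symptom, DIARY_SYMPTOMS), d$week + 1L)] <- d$rating
    symptom_diary(d$subject[1L], d$arm[1L], d$sex[1L], m)
  })
}

#' Write symptom diaries to a long-format CSV
#'
#' Inverse of [read_symptom_diaries()]; missing cells are omitted from the
#' file rather than written as blank rows.
#'
#' @param diaries List of [symptom_diary()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_symptom_diaries <- function(diaries, path) {
  rows <- lapply(diaries, function(d) {
    long <- expand.grid(symptom = DIARY_SYMPTOMS, week = WEEKS,
                        stringsAsFactors = FALSE)
    long$rating <- as.vector(d$ratings)
    long <- long[!is.na(long$rating), , drop = FALSE]
    data.frame(subject = d$subject_id, arm = d$arm, sex = d$sex,
               dose_g_per_day = d$dose_g_per_day, week = long$week,
               symptom = long$symptom, rating = long$rating,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$week, match(out$symptom, DIARY_SYMPTOMS)), ]
  write_table_csv(out, path)
}
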