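#' Read a fecal pH / short-chain fatty acid panel
#'
#' Long table with columns `subject`, `timepoint` (baseline/week6), `ph`,
#' `total`, `acetate`, `propionate`, `butyrate`; SCFA concentrations in
#' umol/g wet feces.
#'
#' @param path Delimited file.
#' @return Data frame with validated columns.
#' @export
read_metabolites <- function(path) {
  df <- read_table_auto(path)
  need <- c("subject", "timepoint", "ph", "total", "acetate", "propionate",
            "butyrate")
  if (!all(need %in% names(df))) {
    stop_validation("metabolite file must have columns ",
                    paste(need, collapse = ", "))
  }
  if (!all(df$timepoint %in% c("baseline", "week6"))) {
    stop_validation("metabolite timepoint must be baseline or week6")
  }
  if (any(df$ph <= 0 | df$ph >= 14)) stop_validation("pH outside (0, 14)")
  scfa <- as.matrix(df[, c("total", "acetate", "propionate", "butyrate")])
  if (any(scfa < 0)) stop_validation("negative SCFA concentration")
  if (any(df$total + 1e-9 < pmax(df$acetate, df$propionate, df$butyrate))) {
    stop_validation("total SCFA smaller than a component")
  }
  df$subject <- as.character(df$subject)
  df
}

#' Week-6-minus-baseline shifts of pH and SCFA concentrations
#'
#' @param panel Data frame from [read_metabolites()].
#' @return Data frame, one row per subject with both timepoints: columns
#'   `ph`, `total`, `acetate`, `propionate`, `butyrate` as shifts
#'   (acidification is a negative pH shift).
#' @export
metabolite_shifts <- function(panel) {
  vars <- c("ph", "total", "acetate", "propionate", "butyrate")
  subs <- intersect(panel$subject[panel$timepoint == "baseline"],
                    panel$subject[panel$timepoint == "week6"])
  i0 <- match(paste(subs, "baseline"), paste(panel$subject, panel$timepoint))
  i6 <- match(paste(subs, "week6"), paste(panel$subject, panel$timepoint))
  out <- panel[i6, vars] - panel[i0, vars]
  rownames(out) <- NULL
  cbind(data.frame(subject = subs, stringsAsFactors = FALSE), out)
}

#' Read a one-month diet-history profile table
#'
#' One row per subject: `subject`, `energy_kcal`, then daily intake columns;
#' at minimum `meat_alternatives_servings`, `whole_grains_servings`,
#' `cholesterol_mg`, `dietary_fiber_g`.
#'
#' @param path Delimited file.
#' @return Data frame with validated columns.
#' @export
read_diet <- function(path) {
  df <- read_table_auto(path)
  need <- c("subject", "energy_kcal", "meat_alternatives_servings",
            "whole_grains_servings", "cholesterol_mg", "dietary_fiber_g")
  if (!all(need %in% names(df))) {
    stop_validation("diet file must have columns ", paste(need, collapse = ", "))
  }
  if (any(df$energy_kcal <= 0)) stop_validation("energy_kcal must be > 0")
  intake <- as.matrix(df[, setdiff(names(df), c("subject", "energy_kcal"))])
  if (any(intake < 0)) stop_validation("negative intake value")
  df$subject <- as.character(df$subject)
  df
}

#' Calorie-adjust diet-history intakes
#'
#' Two standard energy adjustments: nutrient density (amount per 1000 kcal)
#' and the residual method (residual from the cohort regression of intake on
#' energy, recentred at the cohort mean intake).  Density is the default;
#' the residual method needs the whole cohort at once.
#'
#' @param profiles Data frame from [read_diet()] (whole cohort).
#' @param method `"density"` or `"residual"`.
#' @return Data frame of adjusted intakes (same columns, minus energy) plus
#'   an `adjustment` attribute recording the method.
#' @export
calorie_adjust <- function(profiles, method = c("density", "residual")) {
  method <- match.arg(method)
  if (any(profiles$energy_kcal <= 0)) stop_validation("energy_kcal must be > 0")
  items <- setdiff(names(profiles), c("subject", "energy_kcal"))
  adj <- profiles[, items, drop = FALSE]
  if (method == "density") {
    adj[] <- lapply(adj, function(x) x * 1000 / profiles$energy_kcal)
  } else {
    energy <- profiles$energy_kcal
    adj[] <- lapply(adj, function(x) {
      if (stats::var(energy) == 0) return(x)  # degenerate: regression undefined
      residuals(lm(x ~ energy)) + mean(x)
    })
  }
  out <- cbind(data.frame(subject = profiles$subject, stringsAsFactors = FALSE),
               adj)
  attr(out, "adjustment") <- method
  out
}

#' Ratio of two calorie-adjusted diet items
#'
#' Animal-to-plant contrasts such as meat/meat-alternatives : whole grains or
#' dietary cholesterol : dietary fiber.  Subjects with a zero denominator get
#' `NA` and are excluded pairwise from that ratio's correlations.
#'
#' @param adjusted Data frame from [calorie_adjust()].
#' @param numerator_item,denominator_item Column names.
#' @return Named numeric vector of ratios (names = subject ids).
#' @export
diet_ratio <- function(adjusted, numerator_item, denominator_item) {
  num <- adjusted[[numerator_item]]
  den <- adjusted[[denominator_item]]
  if (is.null(num) || is.null(den)) stop_validation("unknown diet item")
  r <- ifelse(den > 0, num / den, NA_real_)
  setNames(r, adjusted$subject)
}

#' Standard diet feature matrix (adjusted intakes plus the two ratios)
#'
#' @param profiles Data frame from [read_diet()].
#' @param method Energy-adjustment method, see [calorie_adjust()].
#' @return Data frame: subject, calorie-adjusted intakes, `meat:wgrain` and
#'   `chole:DF` ratios.
#' @export
diet_features <- function(profiles, method = "density") {
  adj <- calorie_adjust(profiles, method)
  adj[["meat:wgrain"]] <- unname(diet_ratio(adj, "meat_alternatives_servings",
                                            "whole_grains_servings"))
  adj[["chole:DF"]] <- unname(diet_ratio(adj, "cholesterol_mg",
                                         "dietary_fiber_g"))
  attr(adj, "adjustment") <- method
  adj
}
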