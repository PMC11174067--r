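#' Configuration for a synthetic fiber-trial cohort
#'
#' Describes a two-arm randomized trial of a fermentable fiber (AX) against
#' a non-fermentable control (MCC): arm sizes and sex splits fix the dose
#' labels (25 g/day female, 35 g/day male), and the effect block wires the
#' planted associations that the analysis pipeline is expected to recover.
#' `null_mode = TRUE` severs every planted link (for type-I calibration)
#' while leaving the marginal data structure intact.
#'
#' @param n_ax,n_mcc Arm sizes (default 15 and 16).
#' @param n_female_ax,n_female_mcc Females per arm (default about two thirds:
#'   10/15 and 11/16 at the default arm sizes); the remainder are male.
#' @param seed Integer master seed; every random block derives from it.
#' @param adapt_peak_week Week at which the mean symptom rise peaks.
#' @param mean_peak_composite_rise Expected composite-rating rise (points)
#'   at the peak week for a typical AX subject.
#' @param adapt_rate Strength with which the adaptation latent accelerates
#'   the late-trial symptom decay.
#' @param tolerance_effect_rho Target magnitude of the realized Spearman
#'   correlation between baseline abundance of the planted
#'   *B. longum*-like taxon and the composite AUC adaptation score.
#' @param bifido_baseline_logmean,bifido_baseline_logsd Log-scale location
#'   and spread of the planted taxon's baseline abundance.
#' @param acetate_link,ph_link Linear wiring of the fecal acetate shift
#'   (positive) and pH shift (negative) to the planted latents.
#' @param diet_gradient Wiring of the animal:plant diet gradient to symptom
#'   severity.
#' @param null_mode Logical; force every link to zero.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_ax = 15L, n_mcc = 16L, n_female_ax = NULL,
                          n_female_mcc = NULL, seed = 1L,
                          adapt_peak_week = 2L,
                          mean_peak_composite_rise = 4,
                          adapt_rate = 1,
                          tolerance_effect_rho = 0.7,
                          bifido_baseline_logmean = log(0.03),
                          bifido_baseline_logsd = 1,
                          acetate_link = 0.9, ph_link = -0.7,
                          diet_gradient = 0.75, null_mode = FALSE) {
  if (n_ax < 4L || n_mcc < 4L) stop_validation("need >= 4 subjects per arm")
  # trial default: ~2/3 female per arm (10/15 AX, 11/16 MCC)
  n_female_ax <- n_female_ax %||% round(n_ax * 2 / 3)
  n_female_mcc <- n_female_mcc %||% round(n_mcc * 11 / 16)
  if (n_female_ax < 0L || n_female_ax > n_ax ||
      n_female_mcc < 0L || n_female_mcc > n_mcc) {
    stop_validation("sex split must lie within the arm size")
  }
  if (abs(tolerance_effect_rho) >= 1) {
    stop_validation("requested |rho| >= 1 is infeasible")
  }
  links <- c(adapt_rate = adapt_rate, acetate_link = acetate_link,
             ph_link = ph_link, diet_gradient = diet_gradient)
  if (!all(is.finite(links))) stop_validation("link parameters must be finite")
  structure(list(n_ax = as.integer(n_ax), n_mcc = as.integer(n_mcc),
                 n_female_ax = as.integer(n_female_ax),
                 n_female_mcc = as.integer(n_female_mcc),
                 seed = as.integer(seed),
                 adapt_peak_week = as.integer(adapt_peak_week),
                 mean_peak_composite_rise = mean_peak_composite_rise,
                 adapt_rate = adapt_rate,
                 tolerance_effect_rho = tolerance_effect_rho,
                 bifido_baseline_logmean = bifido_baseline_logmean,
                 bifido_baseline_logsd = bifido_baseline_logsd,
                 acetate_link = acetate_link, ph_link = ph_link,
                 diet_gradient = diet_gradient, null_mode = isTRUE(null_mode)),
            class = "cohort_config")
}

# Ordinal thresholding of the latent trajectories attenuates rank
# correlations; the latent wiring is inflated by this factor (estimated once
# by simulation during development, frozen here) so the realized Spearman
# approaches the configured target.
ORDINAL_ATTENUATION <- 0.72

# Latent wiring of symptom severity to the planted taxon (log-abundance
# z-score); negative: more B. longum-like taxon, milder symptoms.
SEVERITY_LINK <- -0.55

# Static taxon universe: 46 OTUs across 5 phyla, with a 6-member CARG
# around the planted fiber degrader.
cohort_taxa <- function() {
  lin <- c(
    B_longum_like       = "Actinobacteria;Bifidobacteriaceae;Bifidobacterium",
    Blautia_obeum_like  = "Firmicutes;Lachnospiraceae;Blautia",
    Subdoligranulum_like = "Firmicutes;Ruminococcaceae;Subdoligranulum",
    Prevotella_copri_like = "Bacteroidetes;Prevotellaceae;Prevotella",
    B_adolescentis_like = "Actinobacteria;Bifidobacteriaceae;Bifidobacterium",
    Collinsella_like    = "Actinobacteria;Coriobacteriaceae;Collinsella")
  background <- list(
    c("Firmicutes", "Lachnospiraceae", "Blautia"),
    c("Firmicutes", "Lachnospiraceae", "Roseburia"),
    c("Firmicutes", "Lachnospiraceae", "Coprococcus"),
    c("Firmicutes", "Ruminococcaceae", "Faecalibacterium"),
    c("Firmicutes", "Ruminococcaceae", "Ruminococcus"),
    c("Firmicutes", "Oscillospiraceae", "Oscillibacter"),
    c("Firmicutes", "Veillonellaceae", "Dialister"),
    c("Bacteroidetes", "Bacteroidaceae", "Bacteroides"),
    c("Bacteroidetes", "Porphyromonadaceae", "Parabacteroides"),
    c("Bacteroidetes", "Odoribacteraceae", "Odoribacter"),
    c("Bacteroidetes", "Rikenellaceae", "Alistipes"),
    c("Actinobacteria", "Bifidobacteriaceae", "Bifidobacterium"),
    c("Proteobacteria", "Enterobacteriaceae", "Escherichia"),
    c("Proteobacteria", "Sutterellaceae", "Sutterella"),
    c("Verrucomicrobia", "Akkermansiaceae", "Akkermansia"))
  n_bg <- 40L
  bg_lin <- vapply(seq_len(n_bg), function(i) {
    paste(background[[(i - 1L) %% length(background) + 1L]], collapse = ";")
  }, character(1))
  names(bg_lin) <- sprintf("OTU%02d", seq_len(n_bg) + 6L)
  taxonomy <- c(lin, bg_lin)
  carg_map <- c(
    setNames(rep("CARG1_like", 6L),
             c("B_longum_like", "Blautia_obeum_like", "Subdoligranulum_like",
               "OTU07", "OTU10", "OTU12")),
    setNames(rep("CARG2", 4L), c("OTU08", "OTU09", "OTU11", "OTU13")),
    setNames(rep("CARG3", 4L), c("OTU14", "OTU15", "OTU16", "OTU17")),
    setNames(rep("CARG4", 3L), c("OTU18", "OTU19", "OTU20")),
    setNames(rep("CARG5", 3L), c("OTU21", "OTU22", "OTU23")),
    setNames(rep("CARG6", 3L), c("Prevotella_copri_like", "OTU24", "OTU25")),
    setNames(rep("CARG7", 3L), c("B_adolescentis_like", "Collinsella_like",
                                 "OTU26")))
  whitelist <- c("B_longum_like", "Blautia_obeum_like", "Subdoligranulum_like",
                 "Prevotella_copri_like", "B_adolescentis_like",
                 "Collinsella_like", "OTU07", "OTU08", "OTU10", "OTU12",
                 "OTU14", "OTU18", "OTU21", "OTU24", "OTU26")
  base_logmean <- setNames(seq(log(0.05), log(0.0008),
                               length.out = length(taxonomy)),
                           names(taxonomy))
  base_logmean["B_longum_like"] <- NA_real_  # set from config
  list(taxonomy = taxonomy, carg_map = carg_map, whitelist = whitelist,
       base_logmean = base_logmean)
}

clamp_rating <- function(x) pmin(4, pmax(0, round(x)))

#' Generate a complete synthetic trial dataset
#'
#' Produces every derived table the analysis pipeline consumes: weekly
#' symptom diaries with a rise-then-adapt trajectory in the AX arm,
#' compositional fecal abundance tables at baseline/week 1/week 6 (46 taxa,
#' 5 phyla, log-normal draws closed to the simplex), an ex vivo
#' active-consortium ASV table, fecal pH/SCFA panels, and a baseline
#' diet-history table.  A *B. longum*-like OTU nested in a 6-member CARG is
#' wired so that higher baseline abundance means milder symptoms and faster
#' adaptation, with correlated acetate/pH shifts and an animal:plant diet
#' gradient wired to severity.  All randomness flows from `config$seed`
#' through per-block substreams, so regenerating with the same seed is
#' byte-identical and adding a block never perturbs earlier ones.
#'
#' @param config A [cohort_config()].
#' @return List: `diaries`, `fecal` ([abundance_table()] with
#'   baseline/week1/week6 samples), `exvivo` (ASV-level table), `metabolites`,
#'   `diet`, `taxonomy`, `carg_map`, `whitelist`, `config`, and `latents`
#'   (the per-subject generative latents, for diagnostics only).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  block_seeds <- sample.int(.Machine$integer.max - 1L, 6L)
  names(block_seeds) <- c("latents", "symptoms", "abundance", "exvivo",
                          "metabolites", "diet")

  n <- config$n_ax + config$n_mcc
  subject <- c(sprintf("AX%02d", seq_len(config$n_ax)),
               sprintf("MCC%02d", seq_len(config$n_mcc)))
  arm <- rep(c("AX", "MCC"), c(config$n_ax, config$n_mcc))
  sex <- c(rep(c("F", "M"), c(config$n_female_ax,
                              config$n_ax - config$n_female_ax)),
           rep(c("F", "M"), c(config$n_female_mcc,
                              config$n_mcc - config$n_female_mcc)))

  ## -- latent block: planted taxon abundance and tolerance propensities ----
  set.seed(block_seeds["latents"])
  b <- rnorm(n, config$bifido_baseline_logmean, config$bifido_baseline_logsd)
  z <- (b - config$bifido_baseline_logmean) / config$bifido_baseline_logsd
  eps_u <- rnorm(n); eps_v <- rnorm(n)
  rho_lat <- min(0.995, abs(config$tolerance_effect_rho) / ORDINAL_ATTENUATION)
  wired <- (arm == "AX") & !config$null_mode
  u <- ifelse(wired, rho_lat * z + sqrt(1 - rho_lat^2) * eps_u, eps_u)
  v <- ifelse(wired, SEVERITY_LINK * z + sqrt(1 - SEVERITY_LINK^2) * eps_v,
              eps_v)

  ## -- symptom block: ordinal weekly diaries ------------------------------
  set.seed(block_seeds["symptoms"])
  peak <- config$adapt_peak_week
  early <- exp(-0.5 * ((1:3 - peak) / 1.2)^2)     # rise peaking at `peak`
  late_base <- c(0.75, 0.60, 0.50)
  wt <- c(overall = 0.38, flatulence = 0.45, bloating = 0.33,
          stomachache = 0.22)
  diaries <- vector("list", n)
  for (i in seq_len(n)) {
    if (arm[i] == "AX") {
      R <- config$mean_peak_composite_rise * exp(0.3 * v[i] - 0.3^2 / 2)
      # smooth bounded decay in (0, 1.3): strictly decreasing in the
      # adaptation latent, no saturation plateau
      decay <- 1.3 * stats::plogis(-(0.5 + config$adapt_rate * 1.3 * u[i]))
    } else {
      R <- 0.8 * exp(0.3 * v[i] - 0.3^2 / 2)
      decay <- 1.3 * stats::plogis(-(0.3 + 0.3 * u[i]))
    }
    shape <- c(early, late_base * decay)
    base <- rbinom(4L, 1L, 0.15)
    m <- matrix(NA_real_, 4L, 7L)
    m[, 1L] <- base
    for (s in 1:4) {
      m[s, 2:7] <- clamp_rating(base[s] + R * wt[s] * shape + rnorm(6, 0, 0.25))
    }
    diaries[[i]] <- symptom_diary(subject[i], arm[i], sex[i], m)
  }
  names(diaries) <- subject

  ## -- abundance block: compositional fecal tables ------------------------
  set.seed(block_seeds["abundance"])
  taxa <- cohort_taxa()
  taxa$base_logmean["B_longum_like"] <- config$bifido_baseline_logmean
  tax_ids <- names(taxa$taxonomy)
  n_tax <- length(tax_ids)
  subj_eff <- matrix(rnorm(n * n_tax, 0, 0.8), n, n_tax,
                     dimnames = list(subject, tax_ids))
  subj_eff[, "B_longum_like"] <- b - config$bifido_baseline_logmean
  carg1 <- setdiff(names(taxa$carg_map)[taxa$carg_map == "CARG1_like"],
                   "B_longum_like")
  tps <- c("baseline", "week1", "week6")
  rows <- vector("list", length(tps))
  for (t in seq_along(tps)) {
    la <- matrix(rep(taxa$base_logmean, each = n), n, n_tax) + subj_eff +
      matrix(rnorm(n * n_tax, 0, 0.5), n, n_tax)
    colnames(la) <- tax_ids
    la[, "B_longum_like"] <- b +
      rnorm(n, 0, 0.25) + if (tps[t] == "baseline") 0 else
        ifelse(arm == "AX", 0.8, 0)                 # AX bloom of the degrader
    if (tps[t] != "baseline" && !config$null_mode) {
      la[, carg1] <- la[, carg1] + ifelse(arm == "AX", 0.4 + 0.25 * z, 0)
    }
    a <- exp(la)
    rows[[t]] <- a / rowSums(a)
  }
  vals <- do.call(rbind, rows)
  fecal <- abundance_table(vals,
                           sample_ids = paste(rep(subject, length(tps)),
                                              rep(tps, each = n), sep = "_"),
                           subject_ids = rep(subject, length(tps)),
                           timepoint = rep(tps, each = n),
                           level = "otu", taxonomy = taxa$taxonomy,
                           carg_map = taxa$carg_map)

  ## -- ex vivo block: active-consortium ASV table -------------------------
  set.seed(block_seeds["exvivo"])
  asv_ids <- c("ASV_B_longum_like",
               sprintf("ASV%02d", 2:30))
  degrader <- c(TRUE, rep(c(TRUE, FALSE), length.out = 29L))
  la <- matrix(rep(seq(log(0.06), log(0.002), length.out = 30L), each = n),
               n, 30L) +
    matrix(rnorm(n * 30L, 0, 0.7), n, 30L) +
    matrix(rep(ifelse(degrader, 0.5, -0.5), each = n), n, 30L)
  colnames(la) <- asv_ids
  la[, "ASV_B_longum_like"] <- b + 0.6 + rnorm(n, 0, 0.3)
  a <- exp(la)
  asv_tax <- setNames(rep("", 30L), asv_ids)
  asv_tax["ASV_B_longum_like"] <- "Actinobacteria;Bifidobacteriaceae;Bifidobacterium"
  exvivo <- abundance_table(a / rowSums(a),
                            sample_ids = paste0(subject, "_exvivo"),
                            subject_ids = subject,
                            timepoint = rep("exvivo", n),
                            level = "asv", taxonomy = asv_tax)

  ## -- metabolite block: fecal pH and SCFA panels -------------------------
  set.seed(block_seeds["metabolites"])
  ph0 <- rnorm(n, 6.9, 0.25)
  ph_shift <- ifelse(wired, config$ph_link * 0.25 * z, 0) + rnorm(n, 0, 0.18)
  ac0 <- exp(rnorm(n, log(55), 0.25))
  ac_shift <- ifelse(wired, config$acetate_link * 10 * u, 0) + rnorm(n, 0, 7)
  pr0 <- exp(rnorm(n, log(20), 0.3))
  pr_shift <- ifelse(arm == "AX", rnorm(n, 3, 4), rnorm(n, 0, 4))
  bu0 <- exp(rnorm(n, log(15), 0.3))
  bu_shift <- rnorm(n, 0, 3)
  mk_panel <- function(tp, ph, ac, pr, bu) {
    ac <- pmax(ac, 0.1); pr <- pmax(pr, 0.1); bu <- pmax(bu, 0.1)
    data.frame(subject = subject, timepoint = tp,
               ph = pmin(13.9, pmax(0.1, ph)),
               total = ac + pr + bu, acetate = ac, propionate = pr,
               butyrate = bu, stringsAsFactors = FALSE)
  }
  metabolites <- rbind(mk_panel("baseline", ph0, ac0, pr0, bu0),
                       mk_panel("week6", ph0 + ph_shift, ac0 + ac_shift,
                                pr0 + pr_shift, bu0 + bu_shift))

  ## -- diet block: one-month baseline diet history ------------------------
  set.seed(block_seeds["diet"])
  diet_wired <- if (config$null_mode) rep(0, n) else v
  energy <- pmax(1200, rnorm(n, 2150, 350))
  wg <- exp(rnorm(n, log(1.3), 0.45))
  log_ratio <- log(1.6) + 0.8 * config$diet_gradient * diet_wired +
    rnorm(n, 0, 0.45)
  meat <- wg * exp(log_ratio)
  chole <- 250 * exp(0.4 * config$diet_gradient * diet_wired +
                       rnorm(n, 0, 0.35))
  df_g <- 18 * exp(-0.3 * config$diet_gradient * diet_wired +
                     rnorm(n, 0, 0.3))
  diet <- data.frame(subject = subject, energy_kcal = energy,
                     meat_alternatives_servings = meat,
                     whole_grains_servings = wg,
                     cholesterol_mg = chole, dietary_fiber_g = df_g,
                     stringsAsFactors = FALSE)

  list(diaries = diaries, fecal = fecal, exvivo = exvivo,
       metabolites = metabolites, diet = diet,
       taxonomy = taxa$taxonomy, carg_map = taxa$carg_map,
       whitelist = taxa$whitelist, config = config,
       latents = data.frame(subject = subject, arm = arm, b = b, z = z,
                            u = u, v = v, stringsAsFactors = FALSE))
}

#' Planted ground-truth effects of a synthetic cohort
#'
#' Machine-readable descriptors of every association wired into the
#' generator for the given configuration: feature, score, window and the
#' expected correlation sign.  Empty under `null_mode`.
#'
#' @param config A [cohort_config()].
#' @return Data frame: `feature_id`, `feature_class`, `score_name`,
#'   `window`, `arm`, `sign`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  empty <- data.frame(feature_id = character(0), feature_class = character(0),
                      score_name = character(0), window = character(0),
                      arm = character(0), sign = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$null_mode) return(empty)
  gt <- list()
  add <- function(f, cl, sc, win, sg) {
    data.frame(feature_id = f, feature_class = cl, score_name = sc,
               window = win, arm = "AX", sign = sg, stringsAsFactors = FALSE)
  }
  rbind(
    add("B_longum_like", "otu", "composite.auc_adaptation", "baseline", +1),
    add("B_longum_like", "otu", "composite.auc_severity", "baseline", -1),
    add("B_longum_like", "otu", "composite.auc_severity", "w13", -1),
    add("ASV_B_longum_like", "asv", "composite.auc_adaptation", "exvivo", +1),
    add("acetate", "scfa", "composite.auc_adaptation", "shift",
        sign(config$acetate_link)),
    add("ph", "ph", "composite.auc_severity", "shift", -sign(config$ph_link)),
    add("meat:wgrain", "diet", "composite.auc_severity", "whole",
        sign(config$diet_gradient)),
    add("meat:wgrain", "diet", "composite.auc_adaptation", "whole",
        -sign(config$diet_gradient)))
}
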