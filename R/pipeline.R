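#' Default run configuration
#'
#' Every analysis decision the pipeline makes is a field here and is
#' serialized into the run manifest, so no default is hidden.
#'
#' @param simulate `NULL` to read inputs from `paths`, or a named list of
#'   [cohort_config()] arguments to generate a synthetic cohort first.
#' @param paths Named list of input files (`diaries`, `abundance`,
#'   `taxonomy`, `cargs`, `whitelist`, `exvivo`, `metabolites`, `diet`);
#'   ignored when `simulate` is given.
#' @param auc_mode AUC severity mode (`"incremental"` or `"raw"`).
#' @param missing Missing-week policy (`"strict"` or `"interpolate"`).
#' @param taxon_filter Mean-abundance screen for taxa/CARGs (fraction).
#' @param asv_filter Mean-abundance screen for active ASVs (fraction).
#' @param pvalue_mode `"approx"`, `"exact"` or `"permutation"`.
#' @param nperm Monte-Carlo permutations when applicable.
#' @param seed Seed recorded in the manifest and used for any Monte-Carlo
#'   p-values (and for simulation when `simulate` lacks its own seed).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = list(), paths = list(),
                       auc_mode = "incremental", missing = "strict",
                       taxon_filter = 0.0015, asv_filter = 0.01,
                       pvalue_mode = "approx", nperm = 9999L, seed = 1L) {
  structure(list(simulate = simulate, paths = paths, auc_mode = auc_mode,
                 missing = missing, taxon_filter = taxon_filter,
                 asv_filter = asv_filter, pvalue_mode = pvalue_mode,
                 nperm = as.integer(nperm), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits every table in the delimited formats the readers consume.
#'
#' @param bundle Output of [generate_cohort()].
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(diaries = file.path(dir, "diaries.csv"),
         abundance = file.path(dir, "abundance.csv"),
         taxonomy = file.path(dir, "taxonomy.csv"),
         cargs = file.path(dir, "cargs.csv"),
         whitelist = file.path(dir, "significant_otus.txt"),
         exvivo = file.path(dir, "exvivo_abundance.csv"),
         exvivo_taxonomy = file.path(dir, "exvivo_taxonomy.csv"),
         metabolites = file.path(dir, "metabolites.csv"),
         diet = file.path(dir, "diet.csv"))
  write_symptom_diaries(bundle$diaries, p["diaries"])
  write_abundance_table(bundle$fecal, p["abundance"], p["taxonomy"], p["cargs"])
  writeLines(bundle$whitelist, p["whitelist"])
  write_abundance_table(bundle$exvivo, p["exvivo"], p["exvivo_taxonomy"])
  write_table_csv(bundle$metabolites, p["metabolites"])
  write_table_csv(bundle$diet, p["diet"])
  invisible(p)
}

read_cohort_inputs <- function(paths) {
  list(diaries = read_symptom_diaries(paths$diaries),
       fecal = read_abundance_table(paths$abundance, paths$taxonomy,
                                    paths$cargs, level = "otu"),
       exvivo = read_abundance_table(paths$exvivo, paths$exvivo_taxonomy,
                                     level = "asv"),
       whitelist = readLines(paths$whitelist),
       metabolites = read_metabolites(paths$metabolites),
       diet = read_diet(paths$diet))
}

#' Run the full tolerance-analysis pipeline
#'
#' Orchestrates simulate (optional) -> diary scoring -> microbiota, ex vivo,
#' metabolite and diet feature engineering -> all association tables, and
#' writes every output plus a manifest (config, package version, seed, file
#' hashes) and a human-readable log into `out_dir`.  Outputs carry no
#' timestamps, so a rerun with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the run manifest and in-memory tables.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    bundle <- generate_cohort(do.call(cohort_config, sim_args))
    input_dir <- file.path(out_dir, "inputs")
    paths <- write_cohort(bundle, input_dir)
    note("simulated cohort with seed ", sim_args$seed)
  } else {
    paths <- config$paths
  }
  inputs <- read_cohort_inputs(as.list(paths))
  arms <- vapply(inputs$diaries, `[[`, character(1), "arm")
  note("read ", length(inputs$diaries), " diaries (AX ", sum(arms == "AX"),
       ", MCC ", sum(arms == "MCC"), ")")

  ## scores ----------------------------------------------------------------
  scores <- score_table(inputs$diaries, auc_mode = config$auc_mode,
                        missing = config$missing)
  flags <- scores[scores$symptom == "composite",
                  c("subject", "arm", "max_severity", "max_adaptation",
                    "reverted")]
  for (s in flags$subject[is.na(flags$reverted)]) {
    note("subject ", s, ": reverted flag undefined (missing weeks)")
  }

  ## community features -----------------------------------------------------
  levels_out <- list()
  for (lvl in c("phylum", "family", "genus", "carg")) {
    agg <- aggregate_taxa(inputs$fecal, lvl)
    levels_out[[lvl]] <- filter_mean_abundance(agg, config$taxon_filter)
  }
  sig <- whitelist_features(inputs$fecal, inputs$whitelist)
  divtab <- diversity_table(inputs$fecal)
  active <- filter_mean_abundance(inputs$exvivo, config$asv_filter,
                                  provenance = "active_asvs")

  ## associations ------------------------------------------------------------
  assoc <- list()
  for (arm in c("AX", "MCC")) {
    for (lvl in names(levels_out)) {
      assoc[[length(assoc) + 1L]] <- windowed_severity_correlations(
        scores, levels_out[[lvl]], arm,
        feature_class = if (lvl == "carg") "carg" else "taxon",
        pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    }
    assoc[[length(assoc) + 1L]] <- windowed_severity_correlations(
      scores, sig, arm, feature_class = "otu",
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    # diversity: per-window per-sample Shannon/richness
    div_wide <- list()
    for (win in c("week1", "week6")) {
      d <- divtab[divtab$timepoint == win, c("subject", "shannon", "richness")]
      names(d)[2:3] <- paste0(c("shannon", "richness"), "_", win)
      div_wide[[win]] <- d
    }
    divm <- merge(div_wide$week1, div_wide$week6, by = "subject", all = TRUE)
    for (win in c("w13", "w46")) {
      tp <- if (win == "w13") "week1" else "week6"
      sub <- divm[, c("subject", paste0(c("shannon", "richness"), "_", tp))]
      names(sub) <- c("subject", "shannon", "richness")
      sc_arm <- scores[scores$arm == arm, , drop = FALSE]
      rows <- lapply(SCORE_SYMPTOMS, function(sym) {
        sr <- sc_arm[sc_arm$symptom == sym, , drop = FALSE]
        sv <- setNames(segment_severity(sr, win), sr$subject)
        common <- intersect(names(sv), sub$subject)
        fmat <- as.matrix(sub[match(common, sub$subject),
                              c("shannon", "richness"), drop = FALSE])
        blk <- run_block(sv[common], fmat, config$pvalue_mode, config$nperm,
                         seed = config$seed + match(sym, SCORE_SYMPTOMS))
        do.call(rbind, lapply(1:2, function(j) {
          association_row(c("shannon", "richness")[j], "diversity",
                          paste0(sym, ".auc_severity"), win, arm,
                          list(rho = blk$rho[j], p = blk$p[j], n = blk$n[j],
                               flag = blk$flag[j]))
        }))
      })
      assoc[[length(assoc) + 1L]] <- do.call(rbind, rows)
    }
    # baseline and shift profiles of significant OTUs and CARGs
    base_idx <- inputs$fecal$timepoint == "baseline"
    base_df <- cbind(data.frame(subject = inputs$fecal$subject_ids[base_idx]),
                     as.data.frame(inputs$fecal$values[base_idx, sig$feature_ids,
                                                       drop = FALSE]))
    carg_all <- aggregate_taxa(inputs$fecal, "carg")
    carg_ids <- setdiff(carg_all$feature_ids, "unclassified")
    carg_base <- cbind(data.frame(subject = carg_all$subject_ids[carg_all$timepoint == "baseline"]),
                       as.data.frame(carg_all$values[carg_all$timepoint == "baseline",
                                                     carg_ids, drop = FALSE]))
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, base_df, "otu", "baseline", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, carg_base, "carg", "baseline", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    sh_otu <- shift_table(subset_abundance(inputs$fecal, features = sig$feature_ids))
    sh_carg <- shift_table(subset_abundance(carg_all, features = carg_ids))
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, sh_otu, "otu", "shift", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, sh_carg, "carg", "shift", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    # ex vivo active ASVs
    ex_df <- cbind(data.frame(subject = active$table$subject_ids),
                   as.data.frame(active$table$values))
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, ex_df, "asv", "exvivo", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    # pH and SCFA shifts
    msh <- metabolite_shifts(inputs$metabolites)
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, msh, setNames(c("ph", rep("scfa", 4L)),
                            c("ph", "total", "acetate", "propionate",
                              "butyrate")),
      "shift", arm, pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
    # diet
    dft <- diet_features(inputs$diet)
    assoc[[length(assoc) + 1L]] <- profile_correlations(
      scores, dft, "diet", "whole", arm,
      pvalue_mode = config$pvalue_mode, nperm = config$nperm,
      perm_seed = config$seed)
  }
  results <- do.call(rbind, c(assoc, make.row.names = FALSE))
  fig2 <- per_week_arm_tests(inputs$diaries)
  adapt <- rbind(adaptation_tests(scores, "AX"), adaptation_tests(scores, "MCC"))
  adapt$arm <- rep(c("AX", "MCC"), each = nrow(adapt) / 2)

  ## outputs ----------------------------------------------------------------
  write_results(results, scores, out_dir)
  write_table_csv(fig2, file.path(out_dir, "fig2_per_week_arm_tests.csv"))
  write_table_csv(adapt, file.path(out_dir, "fig2_adaptation_tests.csv"))
  write_table_csv(flags, file.path(out_dir, "adapted_flags.csv"))
  write_table_csv(divtab, file.path(out_dir, "diversity.csv"))
  by_fig <- list(fig3_taxa = results$window %in% c("w13", "w46"),
                 fig4_baseline_shift_exvivo =
                   results$window %in% c("baseline", "shift", "exvivo") &
                   results$feature_class %in% c("otu", "carg", "asv"),
                 fig5_ph_scfa = results$feature_class %in% c("ph", "scfa"),
                 fig6_diet = results$feature_class == "diet")
  for (nm in names(by_fig)) {
    write_table_csv(results[by_fig[[nm]], , drop = FALSE],
                    file.path(out_dir, paste0(nm, ".csv")))
  }
  out_files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                            c("manifest.json", "log.txt")))
  manifest <- list(
    package = "fibertol",
    version = as.character(packageVersion("fibertol")),
    config = unclass(config),
    seed = config$seed,
    files = as.list(setNames(unname(md5sum(file.path(out_dir, out_files))),
                             out_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(manifest = manifest, scores = scores, results = results,
                 fig2 = fig2, adaptation = adapt, flags = flags))
}
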