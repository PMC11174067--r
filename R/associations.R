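#' Significance tier for an association cell
#'
#' Compositional feature classes (taxon, carg, otu, asv, diversity) use the
#' stricter alpha of 0.01 with "approached" meaning p < 0.05, to curb the
#' multiplicity of taxon-level testing; pH/SCFA and diet cells use 0.05 with
#' "approached" meaning p < 0.10.
#'
#' @param p Raw p-value(s); `NA` maps to `"ns"`.
#' @param feature_class One of `"taxon"`, `"carg"`, `"otu"`, `"asv"`,
#'   `"diversity"`, `"ph"`, `"scfa"`, `"diet"`.
#' @return Character vector: `"significant"`, `"approached"` or `"ns"`.
#' @export
assign_tier <- function(p, feature_class) {
  strict <- feature_class %in% c("taxon", "carg", "otu", "asv", "diversity")
  alpha <- if (strict) 0.01 else 0.05
  near <- if (strict) 0.05 else 0.10
  out <- rep("ns", length(p))
  out[!is.na(p) & p < near] <- "approached"
  out[!is.na(p) & p < alpha] <- "significant"
  out
}

# One association cell as a data.frame row.
association_row <- function(feature_id, feature_class, score_name, window,
                            arm, res) {
  data.frame(feature_id = feature_id, feature_class = feature_class,
             score_name = score_name, window = window, arm = arm,
             n = res$n %||% NA_integer_, rho = res$rho, p = res$p,
             p_adjusted = res$p, tier = assign_tier(res$p, feature_class),
             flag = res$flag %||% "ok", stringsAsFactors = FALSE)
}

score_vector <- function(scores, symptom, score_field, drop_flagged = TRUE) {
  rows <- scores[scores$symptom == symptom, , drop = FALSE]
  v <- rows[[score_field]]
  if (drop_flagged && score_field == "auc_adaptation") {
    v[rows$complete_resolution | rows$zero_symptom] <- NA_real_
  }
  setNames(v, rows$subject)
}

# Batch Monte-Carlo permutation p-values: one seeded permutation set of the
# score ranks, correlated against every feature column at once.  Exact
# achieved level (1+k)/(B+1); bit-for-bit reproducible from `seed`.
perm_pvalues <- function(sv, fmat, nperm, seed) {
  n <- length(sv)
  rs <- rank(sv)
  rf <- apply(fmat, 2L, rank)
  rho <- as.vector(cor(rs, rf))
  set.seed(seed)
  perm <- matrix(0, nperm, n)
  for (b in seq_len(nperm)) perm[b, ] <- rs[sample.int(n)]
  rho_b <- abs(cor(t(perm), rf))  # nperm x nfeat
  p <- (1 + colSums(rho_b >= rep(abs(rho) - 1e-12, each = nperm))) / (nperm + 1)
  list(rho = rho, p = p, n = n)
}

# Dispatch a block of cells sharing one score vector.  Features containing
# missing values fall back to per-cell computation (pairwise deletion).
run_block <- function(sv, fmat, pvalue_mode, nperm, seed) {
  nf <- ncol(fmat)
  out <- list(rho = rep(NA_real_, nf), p = rep(NA_real_, nf),
              n = rep(NA_integer_, nf), flag = rep("ok", nf))
  ok_s <- !is.na(sv)
  if (pvalue_mode == "permutation" && sum(ok_s) >= 4L) {
    clean <- !vapply(seq_len(nf), function(j) anyNA(fmat[ok_s, j]), logical(1))
    degen <- vapply(seq_len(nf), function(j) {
      stats::var(rank(fmat[ok_s, j])) == 0
    }, logical(1))
    if (stats::var(rank(sv[ok_s])) == 0) {
      out$flag[] <- "zero_variance"; out$n[] <- sum(ok_s)
      return(out)
    }
    batch <- clean & !degen
    if (any(batch)) {
      res <- perm_pvalues(sv[ok_s], fmat[ok_s, batch, drop = FALSE], nperm, seed)
      out$rho[batch] <- res$rho; out$p[batch] <- res$p; out$n[batch] <- res$n
    }
    out$flag[degen] <- "zero_variance"; out$n[degen] <- sum(ok_s)
    rest <- which(!clean & !degen)
  } else {
    rest <- seq_len(nf)
  }
  for (j in rest) {
    res <- run_cell(sv, fmat[, j], pvalue_mode, nperm)
    out$rho[j] <- res$rho; out$p[j] <- res$p; out$n[j] <- res$n
    out$flag[j] <- res$flag %||% "ok"
  }
  out
}

run_cell <- function(sv, fv, pvalue_mode, nperm) {
  keep <- complete.cases(sv, fv)
  if (sum(keep) < 4L) {
    return(list(rho = NA_real_, p = NA_real_, n = sum(keep), flag = "too_few_pairs"))
  }
  spearman(sv[keep], fv[keep],
           method = if (pvalue_mode == "approx") "approx" else pvalue_mode,
           nperm = nperm)
}

#' Windowed correlations between segment severity and fecal abundances
#'
#' Fecal samples are collected at weeks 1 and 6 only, so symptom severity
#' over weeks 1-3 (segment AUC) is paired with the week-1 sample and
#' severity over weeks 4-6 with the week-6 sample.  Each feature x symptom
#' combination therefore yields two heatmap cells per arm.  Executed
#' per arm; subjects missing the matched sample are dropped pairwise.
#'
#' @param scores [score_table()] rows for one arm.
#' @param features A `feature_set` or [abundance_table()] carrying week1 and
#'   week6 samples.
#' @param arm Arm label recorded in the output.
#' @param feature_class Class driving the significance tier (default
#'   `"taxon"`; use `"otu"`/`"carg"` as appropriate).
#' @param symptoms Symptoms to score (default all five including composite).
#' @param pvalue_mode `"approx"` (default), `"exact"` or `"permutation"`.
#' @param nperm Monte-Carlo permutations when `pvalue_mode = "permutation"`.
#' @param perm_seed Seed for the permutation stream (cells are bit-for-bit
#'   reproducible given this seed).
#' @return Data frame of association cells.
#' @export
windowed_severity_correlations <- function(scores, features, arm,
                                           feature_class = "taxon",
                                           symptoms = SCORE_SYMPTOMS,
                                           pvalue_mode = "approx",
                                           nperm = 9999L, perm_seed = 1L) {
  tab <- if (inherits(features, "feature_set")) features$table else features
  scores <- scores[scores$arm == arm, , drop = FALSE]
  out <- vector("list", 0L)
  batch_i <- 0L
  for (win in c("w13", "w46")) {
    tp <- if (win == "w13") "week1" else "week6"
    idx <- tab$timepoint == tp
    vals <- tab$values[idx, , drop = FALSE]
    subj <- tab$subject_ids[idx]
    for (sym in symptoms) {
      rows <- scores[scores$symptom == sym, , drop = FALSE]
      sv <- setNames(segment_severity(rows, win), rows$subject)
      common <- intersect(names(sv), subj)
      fmat <- vals[match(common, subj), , drop = FALSE]
      batch_i <- batch_i + 1L
      blk <- run_block(sv[common], fmat, pvalue_mode, nperm,
                       seed = perm_seed + batch_i)
      for (j in seq_along(tab$feature_ids)) {
        out[[length(out) + 1L]] <- association_row(
          tab$feature_ids[j], feature_class, paste0(sym, ".auc_severity"),
          win, arm, list(rho = blk$rho[j], p = blk$p[j], n = blk$n[j],
                         flag = blk$flag[j]))
      }
    }
  }
  do.call(rbind, out)
}

#' Correlations between tolerance scores and per-subject feature profiles
#'
#' Full cross of features x score types (MAX/AUC severity and adaptation) x
#' symptoms for one arm, where each feature supplies exactly one value per
#' subject: a baseline abundance, a week-6-minus-baseline shift, an ex vivo
#' active-fraction abundance, a pH/SCFA shift or a diet feature.
#'
#' @param scores [score_table()] rows for one arm.
#' @param feature_df Data frame: column `subject` plus one column per
#'   feature.
#' @param feature_class Tier class for every column (e.g. `"otu"`, `"carg"`,
#'   `"asv"`, `"ph"`, `"scfa"`, `"diet"`); may be a named vector per column.
#' @param window Window label recorded on the cells (`"baseline"`,
#'   `"shift"`, `"exvivo"`, or `"whole"`).
#' @param arm Arm label.
#' @param symptoms,pvalue_mode,nperm As in
#'   [windowed_severity_correlations()].
#' @param score_fields Score columns to cross (default all four).
#' @return Data frame of association cells.
#' @export
profile_correlations <- function(scores, feature_df, feature_class, window,
                                 arm, symptoms = SCORE_SYMPTOMS,
                                 score_fields = c("max_severity", "auc_severity",
                                                  "max_adaptation", "auc_adaptation"),
                                 pvalue_mode = "approx", nperm = 9999L,
                                 perm_seed = 1L) {
  scores <- scores[scores$arm == arm, , drop = FALSE]
  feats <- setdiff(names(feature_df), "subject")
  classes <- if (length(feature_class) == 1L) {
    setNames(rep(feature_class, length(feats)), feats)
  } else feature_class[feats]
  out <- vector("list", 0L)
  batch_i <- 0L
  for (sym in symptoms) {
    for (field in score_fields) {
      sv <- score_vector(scores, sym, field)
      common <- intersect(names(sv), feature_df$subject)
      fmat <- as.matrix(feature_df[match(common, feature_df$subject), feats,
                                   drop = FALSE])
      batch_i <- batch_i + 1L
      blk <- run_block(sv[common], fmat, pvalue_mode, nperm,
                       seed = perm_seed + batch_i)
      for (j in seq_along(feats)) {
        out[[length(out) + 1L]] <- association_row(
          feats[j], unname(classes[feats[j]]), paste0(sym, ".", field),
          window, arm, list(rho = blk$rho[j], p = blk$p[j], n = blk$n[j],
                            flag = blk$flag[j]))
      }
    }
  }
  do.call(rbind, out)
}

#' Per-week between-arm rank tests
#'
#' Mann-Whitney comparison of AX vs MCC weekly ratings, symptom by symptom
#' and week by week, with a Bonferroni correction across weeks within each
#' symptom.  This is the trajectory-level between-arm surrogate used in
#' place of longitudinal model fitting, which is delegated to standard
#' statistical software when needed.
#'
#' @param diaries List of [symptom_diary()] objects (both arms).
#' @return Data frame: symptom, week, n_ax, n_mcc, U, p, p_adjusted.
#' @export
per_week_arm_tests <- function(diaries) {
  arms <- vapply(diaries, `[[`, character(1), "arm")
  traj <- function(d, sym) {
    if (sym == "composite") {
      composite_rating(d$ratings["flatulence", ], d$ratings["bloating", ],
                       d$ratings["stomachache", ])
    } else d$ratings[sym, ]
  }
  out <- vector("list", 0L)
  for (sym in SCORE_SYMPTOMS) {
    ax <- vapply(diaries[arms == "AX"], traj, numeric(7), sym)
    mcc <- vapply(diaries[arms == "MCC"], traj, numeric(7), sym)
    rows <- lapply(1:6, function(w) {
      xa <- ax[w + 1L, ]; xm <- mcc[w + 1L, ]
      res <- mann_whitney(xa[!is.na(xa)], xm[!is.na(xm)])
      data.frame(symptom = sym, week = w, n_ax = sum(!is.na(xa)),
                 n_mcc = sum(!is.na(xm)), U = res$U, p = res$p,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    rows$p_adjusted <- bonferroni(rows$p, m = 6L)
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Within-arm adaptation tests
#'
#' Paired Wilcoxon tests of (i) the highest rating in weeks 1-5 against the
#' week-6 rating and (ii) the weeks-1-3 AUC against the weeks-4-6 AUC,
#' Bonferroni corrected across symptoms within each contrast.
#'
#' @param scores [score_table()] rows for one arm.
#' @param arm Arm to test.
#' @return Data frame: contrast, symptom, n, W, p, p_adjusted.
#' @export
adaptation_tests <- function(scores, arm) {
  sc <- scores[scores$arm == arm, , drop = FALSE]
  out <- vector("list", 0L)
  for (sym in SCORE_SYMPTOMS) {
    rows <- sc[sc$symptom == sym, , drop = FALSE]
    # max(w1..5) - week6 is exactly the MAX adaptation score
    d_max <- rows$max_adaptation
    res1 <- wilcoxon_signed_rank(d_max[!is.na(d_max)])
    d_auc <- rows$auc_w13 - rows$auc_w46
    res2 <- wilcoxon_signed_rank(d_auc[!is.na(d_auc)])
    out[[length(out) + 1L]] <- data.frame(
      contrast = c("max_vs_week6", "auc_w13_vs_w46"), symptom = sym,
      n = c(sum(!is.na(d_max)), sum(!is.na(d_auc))),
      W = c(res1$W, res2$W), p = c(res1$p, res2$p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out$p_adjusted <- NA_real_
  for (ct in unique(out$contrast)) {
    i <- out$contrast == ct
    out$p_adjusted[i] <- bonferroni(out$p[i], m = sum(i))
  }
  out
}

#' Write association results and scores to disk
#'
#' Emits one tidy long CSV of all association cells, one heatmap-shaped
#' rho matrix per feature class (features x score.window columns), and the
#' tidy scores table.  Column order is deterministic and the long file
#' round-trips losslessly through [read_results()].
#'
#' @param results Data frame of association cells (rbind of engine outputs).
#' @param scores [score_table()] output.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the association files.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(results, scores, dir, prefix = "associations") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  long_path <- file.path(dir, paste0(prefix, "_long.csv"))
  cols <- c("feature_id", "feature_class", "score_name", "window", "arm",
            "n", "rho", "p", "p_adjusted", "tier", "flag")
  if (nrow(results)) {
    results <- results[do.call(order, results[c("feature_class", "feature_id",
                                                "score_name", "window", "arm")]),
                       cols, drop = FALSE]
  } else {
    results <- results[, cols, drop = FALSE]
  }
  write_table_csv(results, long_path)
  paths <- c(paths, long_path)
  for (cl in unique(results$feature_class)) {
    sub <- results[results$feature_class == cl, , drop = FALSE]
    sub$cell <- paste(sub$score_name, sub$window, sub$arm, sep = ".")
    feats <- unique(sub$feature_id); cells <- unique(sub$cell)
    mat <- matrix(NA_real_, length(feats), length(cells),
                  dimnames = list(feats, cells))
    mat[cbind(match(sub$feature_id, feats), match(sub$cell, cells))] <- sub$rho
    mpath <- file.path(dir, paste0(prefix, "_", cl, "_rho_matrix.csv"))
    write_table_csv(cbind(data.frame(feature_id = feats), as.data.frame(mat)),
                    mpath)
    paths <- c(paths, mpath)
  }
  spath <- file.path(dir, "scores.csv")
  write_table_csv(scores, spath)
  invisible(c(paths, spath))
}

#' Read back the tidy association table written by [write_results()]
#' @param dir,prefix As in [write_results()].
#' @return Data frame of association cells.
#' @export
read_results <- function(dir, prefix = "associations") {
  read_table_auto(file.path(dir, paste0(prefix, "_long.csv")))
}
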