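#' Aggregate a feature-level abundance table to a higher level
#'
#' Sums member features per sample at the requested taxonomic rank (taken
#' from the `"phylum;family;genus"` lineage strings) or per CARG.  Features
#' without an assignment at that rank are pooled into an `"unclassified"`
#' bucket so per-sample totals are conserved exactly.
#'
#' @param table An [abundance_table()] at OTU/ASV level.
#' @param target_level `"phylum"`, `"family"`, `"genus"` or `"carg"`.
#' @return An [abundance_table()] at the target level.
#' @export
aggregate_taxa <- function(table, target_level = c("phylum", "family",
                                                   "genus", "carg")) {
  target_level <- match.arg(target_level)
  fids <- table$feature_ids
  if (target_level == "carg") {
    if (is.null(table$carg_map)) stop_validation("no CARG map attached")
    groups <- table$carg_map[fids]
    groups[is.na(groups)] <- "unclassified"
  } else {
    if (is.null(table$taxonomy)) stop_validation("no taxonomy attached")
    idx <- match(target_level, c("phylum", "family", "genus"))
    lineages <- table$taxonomy[fids]
    groups <- vapply(strsplit(ifelse(is.na(lineages), "", lineages), ";",
                              fixed = TRUE),
                     function(p) if (length(p) >= idx && nzchar(p[idx])) p[idx]
                                 else "unclassified",
                     character(1))
    if (all(groups == "unclassified")) {
      stop_validation("taxonomy strings carry no ", target_level, " rank")
    }
  }
  gl <- sort(unique(groups))
  agg <- vapply(gl, function(g) {
    rowSums(table$values[, groups == g, drop = FALSE])
  }, numeric(nrow(table$values)))
  if (!is.matrix(agg)) agg <- matrix(agg, nrow = 1L, dimnames = list(NULL, gl))
  abundance_table(agg, table$sample_ids, table$subject_ids, table$timepoint,
                  level = target_level)
}

#' Filter features by mean relative abundance across all samples
#'
#' Retains features whose mean relative abundance across every sample in the
#' table (both arms, all timepoints pooled) is strictly greater than
#' `threshold`, the screen used ahead of compositional association testing
#' (0.15% for fecal taxa; 1.0% for metabolically active ASVs).
#'
#' @param table An [abundance_table()].
#' @param threshold Fraction in `[0, 1)`; retention is strict `>`.
#' @param provenance Label recorded on the result.
#' @return A `feature_set`: the filtered table plus filter metadata, feature
#'   ids ordered by descending mean abundance.
#' @export
filter_mean_abundance <- function(table, threshold = 0.0015,
                                  provenance = "all_filtered") {
  stopifnot(threshold >= 0, threshold < 1)
  means <- colMeans(table$values)
  keep <- names(sort(means[means > threshold], decreasing = TRUE))
  structure(list(table = subset_abundance(table, features = keep),
                 feature_ids = keep, mean_abundance = means[keep],
                 provenance = provenance, filter_threshold = threshold,
                 level = table$level),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d %s feature(s), provenance %s, threshold %g\n",
              length(x$feature_ids), x$level, x$provenance, x$filter_threshold))
  invisible(x)
}

#' Restrict a table to an externally supplied feature whitelist
#'
#' Used for the previously identified fiber-responsive ("significant") OTUs,
#' whose derivation is an input, not recomputed here.
#'
#' @param table An [abundance_table()].
#' @param whitelist Character vector of feature ids.
#' @return A `feature_set` with provenance `"significant_otus"`.
#' @export
whitelist_features <- function(table, whitelist) {
  keep <- intersect(table$feature_ids, whitelist)
  if (!length(keep)) stop_validation("whitelist shares no features with table")
  structure(list(table = subset_abundance(table, features = keep),
                 feature_ids = keep,
                 mean_abundance = colMeans(table$values)[keep],
                 provenance = "significant_otus", filter_threshold = NA_real_,
                 level = table$level),
            class = "feature_set")
}

#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum p_i \ln p_i} over nonzero proportions; the input is
#' renormalized internally so any nonnegative vector with positive sum works.
#'
#' @param sample_values Nonnegative numeric vector of abundances.
#' @return Diversity in nats.
#' @export
shannon_index <- function(sample_values) {
  if (any(sample_values < 0)) stop_validation("negative abundance")
  s <- sum(sample_values)
  if (s <= 0) stop_validation("all-zero sample has no diversity")
  p <- sample_values[sample_values > 0] / s
  -sum(p * log(p))
}

#' Observed richness (count of nonzero features)
#' @param sample_values Numeric vector of abundances.
#' @return Integer count of features with abundance > 0.
#' @export
richness <- function(sample_values) sum(sample_values > 0)

#' Per-sample alpha-diversity table
#' @param table An [abundance_table()].
#' @return Data frame: sample_id, subject, timepoint, shannon, richness.
#' @export
diversity_table <- function(table) {
  data.frame(sample_id = table$sample_ids, subject = table$subject_ids,
             timepoint = table$timepoint,
             shannon = apply(table$values, 1L, shannon_index),
             richness = apply(table$values, 1L, richness),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Week-6-minus-baseline shift of one feature for one subject
#'
#' @param table An [abundance_table()] containing that subject's baseline
#'   and week-6 samples.
#' @param subject_id,feature_id Identify the cell.
#' @return `value(week6) - value(baseline)`; `NA` (with a message attribute)
#'   if either timepoint is missing, in which case the subject is excluded
#'   from shift correlations.
#' @export
shift <- function(table, subject_id, feature_id) {
  i0 <- which(table$subject_ids == subject_id & table$timepoint == "baseline")
  i6 <- which(table$subject_ids == subject_id & table$timepoint == "week6")
  if (length(i0) != 1L || length(i6) != 1L) {
    return(structure(NA_real_, note = paste0("subject ", subject_id,
                                             ": missing baseline or week6 sample")))
  }
  unname(table$values[i6, feature_id] - table$values[i0, feature_id])
}

#' Week-6-minus-baseline shifts for all subjects and features
#' @param table An [abundance_table()] with baseline and week6 samples.
#' @return Data frame, one row per subject, one column per feature; subjects
#'   lacking either timepoint are omitted.
#' @export
shift_table <- function(table) {
  subs <- intersect(table$subject_ids[table$timepoint == "baseline"],
                    table$subject_ids[table$timepoint == "week6"])
  i0 <- match(paste(subs, "baseline"), paste(table$subject_ids, table$timepoint))
  i6 <- match(paste(subs, "week6"), paste(table$subject_ids, table$timepoint))
  out <- as.data.frame(table$values[i6, , drop = FALSE] -
                       table$values[i0, , drop = FALSE], check.names = FALSE)
  rownames(out) <- NULL
  cbind(data.frame(subject = subs, stringsAsFactors = FALSE), out)
}
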