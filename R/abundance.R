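#' Construct a relative-abundance table
#'
#' Samples-by-features relative abundance matrix with sample metadata
#' (subject, timepoint), an optional taxonomy map (lineage strings
#' `"phylum;family;genus"`) and an optional co-abundance response group
#' (CARG) membership map.  Feature-level tables (OTU/ASV) must lie on the
#' simplex per sample; aggregated tables may sum to less than 1 only through
#' numerical error.
#'
#' @param values Numeric matrix, samples x features, fractions.
#' @param sample_ids,subject_ids,timepoint Parallel per-sample vectors;
#'   `timepoint` one of `"baseline"`, `"week1"`, `"week6"`, `"exvivo"`.
#' @param level Feature level: `"phylum"`, `"family"`, `"genus"`, `"otu"`,
#'   `"asv"` or `"carg"`.
#' @param taxonomy Named character vector mapping feature id to a
#'   `"phylum;family;genus"` lineage string.
#' @param carg_map Named character vector mapping feature id to CARG id;
#'   membership must be a partition (no feature in two CARGs).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_ids, subject_ids, timepoint,
                            level = c("otu", "asv", "phylum", "family",
                                      "genus", "carg"),
                            taxonomy = NULL, carg_map = NULL) {
  level <- match.arg(level)
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(sample_ids) != n || length(subject_ids) != n || length(timepoint) != n) {
    stop_validation("sample metadata vectors must match nrow(values)")
  }
  if (anyDuplicated(sample_ids)) stop_validation("duplicate sample_id")
  if (!all(timepoint %in% c("baseline", "week1", "week6", "exvivo"))) {
    stop_validation("unknown timepoint label")
  }
  if (any(values < 0)) stop_validation("negative abundance value")
  if (level %in% c("otu", "asv")) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-6)) {
      stop_validation("sample row(s) do not sum to 1 +/- 1e-6: ",
                      paste(sample_ids[abs(rs - 1) > 1e-6][1L], collapse = ", "))
    }
  }
  if (!is.null(carg_map) && anyDuplicated(names(carg_map))) {
    stop_validation("CARG membership must be a partition: duplicated feature ",
                    names(carg_map)[duplicated(names(carg_map))][1L])
  }
  rownames(values) <- sample_ids
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 subject_ids = as.character(subject_ids),
                 timepoint = as.character(timepoint),
                 feature_ids = colnames(values),
                 level = level, taxonomy = taxonomy, carg_map = carg_map),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d features (level %s)\n",
              nrow(x$values), ncol(x$values), x$level))
  invisible(x)
}

#' Read a wide relative-abundance table with taxonomy and CARG maps
#'
#' The main file has samples as rows with metadata columns `sample_id`,
#' `subject`, `timepoint` followed by one column per feature.  Percent
#' encodings are auto-detected (mean row sum > 50) and renormalized to
#' fractions; fraction tables pass through unchanged.
#'
#' @param path Abundance matrix file (CSV/TSV).
#' @param taxonomy_path Optional two-column file `feature_id,lineage`.
#' @param carg_path Optional two-column file `feature_id,carg_id`.  A
#'   feature listed under two CARGs is an error; a CARG feature absent from
#'   the table is dropped with a warning.
#' @param level Feature level of the stored table (default `"otu"`).
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, taxonomy_path = NULL, carg_path = NULL,
                                 level = "otu") {
  df <- read_table_auto(path)
  meta_cols <- c("sample_id", "subject", "timepoint")
  if (!all(meta_cols %in% names(df))) {
    stop_validation("abundance file must have columns ",
                    paste(meta_cols, collapse = ", "))
  }
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(vals < 0)) stop_validation("negative abundance value in ", path)
  if (mean(rowSums(vals)) > 50) vals <- vals / 100  # percent encoding
  vals <- vals / rowSums(vals)                      # close to the simplex
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read_table_auto(taxonomy_path)
    taxonomy <- setNames(as.character(tx$lineage), tx$feature_id)
  }
  carg_map <- NULL
  if (!is.null(carg_path)) {
    cg <- read_table_auto(carg_path)
    if (anyDuplicated(cg$feature_id)) {
      stop_validation("CARG membership must be a partition: duplicated feature ",
                      cg$feature_id[duplicated(cg$feature_id)][1L])
    }
    keep <- cg$feature_id %in% colnames(vals)
    if (any(!keep)) {
      warning("dropping ", sum(!keep),
              " CARG feature(s) absent from the abundance table")
    }
    carg_map <- setNames(as.character(cg$carg_id[keep]), cg$feature_id[keep])
  }
  abundance_table(vals, df$sample_id, df$subject, df$timepoint, level = level,
                  taxonomy = taxonomy, carg_map = carg_map)
}

#' Write an abundance table (plus taxonomy/CARG maps) to CSV
#'
#' @param table An [abundance_table()].
#' @param path Output path for the wide matrix.
#' @param taxonomy_path,carg_path Optional output paths for the maps.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, taxonomy_path = NULL,
                                  carg_path = NULL) {
  df <- data.frame(sample_id = table$sample_ids, subject = table$subject_ids,
                   timepoint = table$timepoint, stringsAsFactors = FALSE,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  write_table_csv(df, path)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy)) {
    write_table_csv(data.frame(feature_id = names(table$taxonomy),
                               lineage = unname(table$taxonomy)), taxonomy_path)
  }
  if (!is.null(carg_path) && !is.null(table$carg_map)) {
    write_table_csv(data.frame(feature_id = names(table$carg_map),
                               carg_id = unname(table$carg_map)), carg_path)
  }
  invisible(path)
}

#' Subset an abundance table by sample or feature
#' @param table An [abundance_table()].
#' @param samples Logical or index vector over samples.
#' @param features Character vector of feature ids to retain.
#' @return An [abundance_table()].
#' @export
subset_abundance <- function(table, samples = NULL, features = NULL) {
  keep_s <- samples %||% seq_along(table$sample_ids)
  keep_f <- features %||% table$feature_ids
  vals <- table$values[keep_s, keep_f, drop = FALSE]
  structure(list(values = vals,
                 sample_ids = table$sample_ids[keep_s],
                 subject_ids = table$subject_ids[keep_s],
                 timepoint = table$timepoint[keep_s],
                 feature_ids = colnames(vals),
                 level = table$level,
                 taxonomy = table$taxonomy, carg_map = table$carg_map),
            class = "abundance_table")
}
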