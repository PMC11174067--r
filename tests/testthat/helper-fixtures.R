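# Shared fixture builders; everything is constructed in code.

# Diary whose four symptom rows are all `traj` unless overridden.
make_diary <- function(traj, subject = "S1", arm = "AX", sex = "F",
                       overrides = list()) {
  m <- matrix(rep(traj, each = 4), 4, 7)
  rownames(m) <- c("overall", "flatulence", "bloating", "stomachache")
  for (nm in names(overrides)) m[nm, ] <- overrides[[nm]]
  symptom_diary(subject, arm, sex, m)
}

# Minimal OTU table: 2 subjects x 3 timepoints x 4 features on the simplex.
make_small_table <- function() {
  vals <- rbind(c(0.50, 0.30, 0.15, 0.05),
                c(0.40, 0.40, 0.10, 0.10),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.10, 0.20, 0.30, 0.40),
                c(0.60, 0.20, 0.10, 0.10),
                c(0.05, 0.15, 0.30, 0.50))
  colnames(vals) <- paste0("OTU", 1:4)
  abundance_table(
    vals,
    sample_ids = paste0("S", rep(1:2, 3), "_", rep(c("baseline", "week1", "week6"), each = 2)),
    subject_ids = rep(c("S1", "S2"), 3),
    timepoint = rep(c("baseline", "week1", "week6"), each = 2),
    level = "otu",
    taxonomy = c(OTU1 = "Actinobacteria;Bifidobacteriaceae;Bifidobacterium",
                 OTU2 = "Firmicutes;Lachnospiraceae;Blautia",
                 OTU3 = "Firmicutes;Lachnospiraceae;Roseburia",
                 OTU4 = "Bacteroidetes;Bacteroidaceae;Bacteroides"),
    carg_map = c(OTU1 = "CARG1", OTU2 = "CARG1", OTU3 = "CARG2"))
}

# Random valid 7-week trajectory on a 0..cap ordinal scale.
random_trajectory <- function(cap = 4) sample(0:cap, 7, replace = TRUE)

# Brute-force oracles -------------------------------------------------------

# All permutations of 1..n (independent of the package's internal helper).
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (p in oracle_perms(n - 1L)) {
      q <- p + (p >= k)
      out[[length(out) + 1L]] <- c(k, q)
    }
  }
  out
}

# Exact two-sided Spearman p by full enumeration of y-permutations.
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  hits <- 0L; total <- 0L
  for (p in oracle_perms(length(y))) {
    total <- total + 1L
    if (abs(cor(rx, ry[p])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
oracle_mw_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(combn(N, n1), 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- min(u_obs, n1 * length(y) - u_obs)
  hi <- max(u_obs, n1 * length(y) - u_obs)
  min(1, mean(u_all <= lo) + mean(u_all >= hi))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns.
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  tot <- m * (m + 1) / 2
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  lo <- min(w_obs, tot - w_obs); hi <- max(w_obs, tot - w_obs)
  min(1, mean(w_all <= lo) + mean(w_all >= hi))
}
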