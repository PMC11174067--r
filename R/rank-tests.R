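#' Spearman rank correlation with small-sample exact option
#'
#' Tie-corrected Spearman correlation: the Pearson correlation of mid-ranks.
#' The default p-value uses the t approximation with n - 2 degrees of
#' freedom (the convention of common statistical packages).  `"exact"`
#' enumerates all permutations of one margin (n <= 8) and `"permutation"`
#' draws seeded Monte-Carlo permutations; both count permutations with
#' |rho| at least as large as observed.
#'
#' @param x,y Paired numeric vectors; pairs with any `NA` are dropped.
#' @param method `"approx"`, `"exact"` or `"permutation"`.
#' @param nperm Monte-Carlo permutation count.
#' @return List: `rho`, `p`, `n`, `flag` (`"ok"` or `"zero_variance"`).
#' @export
spearman <- function(x, y, method = c("approx", "exact", "permutation"),
                     nperm = 9999L) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop_validation("spearman needs at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  }
  rho <- cor(rx, ry)
  p <- switch(method,
    approx = {
      tv <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
      max(2 * pt(-abs(tv), n - 2), .Machine$double.xmin)
    },
    exact = {
      if (n > 8L) stop_validation("exact spearman limited to n <= 8")
      perms <- permutations_of(n)
      # correlation of rx with every permutation of ry, vectorized
      ry_mat <- matrix(ry[perms], nrow = nrow(perms))
      rho_all <- as.vector(cor(rx, t(ry_mat)))
      mean(abs(rho_all) >= abs(rho) - 1e-12)
    },
    permutation = {
      hits <- 0L
      for (b in seq_len(nperm)) {
        if (abs(cor(rx, sample(ry))) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (nperm + 1)
    })
  list(rho = rho, p = p, n = n, flag = "ok")
}

# All n! permutations of 1..n as a matrix (rows = permutations).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mann-Whitney U test (two independent samples)
#'
#' Returns the U statistic for `x` and a two-sided p-value: exact by full
#' enumeration of all choose(n1+n2, n1) rank arrangements when both groups
#' have at most 10 observations and there are no cross-group ties, otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, each with at least 2 observations (error on
#'   an empty group).
#' @return List: `U`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_validation("mann_whitney: empty group")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (n1 <= 10L && n2 <= 10L && !ties) {
    udist <- mw_exact_distribution(n1, n2)
    lo <- min(u, n1 * n2 - u); hi <- max(u, n1 * n2 - u)
    p <- min(1, mean(udist <= lo) + mean(udist >= hi))
    list(U = u, p = p, method = "exact")
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "normal"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    list(U = u, p = min(1, 2 * pnorm(-max(z, 0))), method = "normal")
  }
}

mw_exact_distribution <- function(n1, n2) {
  N <- n1 + n2
  combs <- combn(N, n1)
  colSums(combs) - n1 * (n1 + 1) / 2
}

#' Wilcoxon signed-rank test (paired)
#'
#' Differences of exactly zero are dropped (Wilcoxon convention).  The
#' p-value is exact by enumeration of all 2^m sign assignments (mid-ranks,
#' so ties in |d| are handled) when at most 12 nonzero differences remain,
#' otherwise the normal approximation with tie and continuity corrections.
#' If every difference is zero the test is degenerate and reported as p = 1
#' with `flag = "all_zero"`.
#'
#' @param x,y Paired numeric vectors (`y` defaults to zero, testing the
#'   median of `x`).
#' @return List: `W` (positive-rank sum), `p`, `method`, `flag`.
#' @export
wilcoxon_signed_rank <- function(x, y = 0) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(W = 0, p = 1, method = "degenerate", flag = "all_zero"))
  # a single nonzero difference enumerates to p = 1; no need to refuse it
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  tot <- m * (m + 1) / 2
  if (m <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    wdist <- as.vector(signs %*% r)
    lo <- min(w, tot - w); hi <- max(w, tot - w)
    p <- min(1, mean(wdist <= lo) + mean(wdist >= hi))
    list(W = w, p = p, method = "exact", flag = "ok")
  } else {
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (abs(w - tot / 2) - 0.5) / sqrt(sigma2)
    list(W = w, p = min(1, 2 * pnorm(-max(z, 0))), method = "normal",
         flag = "ok")
  }
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size; defaults to `length(p_values)` and must be at
#'   least that when configured explicitly.
#' @return `min(1, p * m)` per element.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop_validation("bonferroni family size must be >= 1")
  pmin(1, p_values * m)
}
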