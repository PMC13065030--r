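#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both sizes at most 8) the
#' null distribution of U is enumerated exactly over all assignments of the
#' observed values to the two groups (which handles ties naturally); for
#' larger samples a normal approximation with the tie-corrected variance is
#' used (no continuity correction). Identical samples give p = 1.
#'
#' @param x,y numeric samples (nonempty).
#' @return List: `U` (statistic for `x`, with ties counted 1/2),
#'   `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty",
                                     call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  u_stat <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 <= 8L && n2 <= 8L) {
    picks <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u_all - mu)
    p <- mean(dev >= abs(u_stat - mu) - 1e-9)
    return(list(U = u_stat, p_value = p, method = "exact"))
  }

  n <- n1 + n2
  ties <- table(comb)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(list(U = u_stat, p_value = 1, method = "normal"))
  z <- (u_stat - mu) / sqrt(v)
  list(U = u_stat, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic of an r x c contingency table against the chi-square
#' distribution with `(r-1)(c-1)` degrees of freedom. The Yates continuity
#' correction is applied by default to 2 x 2 tables only.
#'
#' @param table integer matrix of counts (no zero margins).
#' @param yates apply the continuity correction (2 x 2 tables only);
#'   default: `TRUE` iff the table is 2 x 2.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_pvalue <- function(table, yates = NULL) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  is2x2 <- all(dim(m) == c(2L, 2L))
  if (is.null(yates)) yates <- is2x2
  if (yates && !is2x2) {
    stop("the Yates correction applies to 2x2 tables only", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(m)
  dev <- abs(m - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the point-probability method: with margins fixed,
#' the hypergeometric probabilities of all tables no more probable than the
#' observed one are summed. Probabilities are computed on the log scale
#' (via `lgamma`) so large counts do not overflow.
#'
#' @param table 2 x 2 integer matrix.
#' @return List: `p_value`, `odds_ratio` (sample odds ratio, possibly
#'   infinite).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0)) {
    stop("need a 2x2 table of nonnegative counts", call. = FALSE)
  }
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lgamma(r1 + 1) - lgamma(k + 1) - lgamma(r1 - k + 1) +
    lgamma(r2 + 1) - lgamma(c1 - k + 1) - lgamma(r2 - c1 + k + 1) -
    (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  p_obs <- logp[k == a]
  keep <- logp <= p_obs + 1e-7          # tolerance for ties in probability
  p <- sum(exp(logp[keep]))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = min(1, p), odds_ratio = or)
}

#' Pairwise Fisher tests with Bonferroni adjustment
#'
#' For every pair of rows of an r x 2 contingency table, runs the two-sided
#' Fisher exact test on the corresponding 2 x 2 sub-table and multiplies
#' the p-value by the number of row pairs `choose(r, 2)`, capping at 1.
#'
#' @param table integer matrix with at least 2 rows and exactly 2 columns;
#'   row names identify the groups.
#' @return data.frame with one row per pair: `row1`, `row2`, `p_raw`,
#'   `p_adjusted`.
#' @export
pairwise_fisher_bonferroni <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) != 2L) {
    stop("need a table with >= 2 rows and exactly 2 columns", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  pairs <- utils::combn(nrow(m), 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    ij <- pairs[, i]
    p <- fisher_exact_2x2(m[ij, , drop = FALSE])$p_value
    data.frame(row1 = rownames(m)[ij[1]], row2 = rownames(m)[ij[2]],
               p_raw = p, p_adjusted = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
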