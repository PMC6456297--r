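#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value follows the point-probability convention: it sums
#' the hypergeometric probabilities of all tables sharing the observed
#' margins whose point probability does not exceed that of the observed
#' table. The reported odds ratio is the sample cross-product ratio
#' `(a*d)/(b*c)`, with `Inf` when `b*c == 0` (reported, not an error).
#'
#' @param table A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise (rows = group, columns = outcome).
#' @return A one-row tibble: `odds_ratio`, `p_value`, and the four counts.
#' @examples
#' fisher_exact(c(6, 16, 1, 24))  # p = 0.040
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  if (sum(m) == 0) abort("all-zero 2x2 table")
  p <- stats::fisher.test(m)$p.value
  or <- if (m[1, 2] * m[2, 1] == 0) {
    if (m[1, 1] * m[2, 2] == 0) NaN else Inf
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  tibble(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
         odds_ratio = or, p_value = min(1, p))
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2, 2))) abort("expected a 2x2 table")
    m <- table
  } else if (is.numeric(table) && length(table) == 4) {
    m <- matrix(table, nrow = 2, byrow = TRUE)
  } else {
    abort("expected a 2x2 matrix or a length-4 count vector")
  }
  if (any(m < 0) || any(m != floor(m))) abort("counts must be non-negative integers")
  m
}

#' Hypergeometric overlap enrichment of two tile sets
#'
#' Given a universe of `N` tiles, a first set of size `K`, a second set of
#' size `n`, and an observed intersection of `k` tiles, reports the expected
#' intersection under independent draws, `K*n/N`, and the upper-tail
#' probability `P(X >= k)` under Hypergeometric(N, K, n). The tail is
#' computed by `phyper`, which is stable far into the tail (p-values around
#' 1e-121 are representable and exact to double precision).
#'
#' @param N Universe size (covered tiles).
#' @param K,n Sizes of the two sets.
#' @param k Observed intersection size.
#' @return A one-row tibble: `N`, `K`, `n`, `k`, `expected`, `p_value`.
#' @examples
#' hypergeom_overlap(263820, 4725, 3156, 299)  # expected 56.5, i.e. "57"
#' @export
hypergeom_overlap <- function(N, K, n, k) {
  for (v in list(N, K, n, k))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != floor(v))
      abort("N, K, n, k must be single non-negative integers")
  if (K > N || n > N || k > min(K, n))
    abort("inconsistent counts: need K <= N, n <= N, k <= min(K, n)")
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(N = N, K = K, n = n, k = k, expected = K * n / N, p_value = p)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples with midrank ties. The exact null
#' distribution is enumerated when both samples have at most 20 observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction (and no continuity correction) is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A one-row tibble: `u` (the U statistic for `x`), `n_x`, `n_y`,
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  # a fully tied pooled sample has zero rank variance; no evidence either way
  p <- if (is.nan(res$p.value)) 1 else res$p.value
  tibble(u = unname(res$statistic), n_x = length(x), n_y = length(y),
         p_value = min(1, p),
         method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved,
#' `q_i >= p_i` and `q_i <= 1` always hold.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with a t-test
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#' @return A one-row tibble: `r`, `n`, `statistic` (t), `p_value`.
#' @export
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    abort("need equal-length samples with at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    abort("undefined correlation: zero variance in a sample")
  res <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(res$estimate), n = length(x),
         statistic = unname(res$statistic), p_value = res$p.value)
}

#' One-sample test of proportions
#'
#' Two-sided normal-approximation score test of `k/n` against `p0`, without
#' continuity correction: `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null proportion, strictly between 0 and 1.
#' @return A one-row tibble: `estimate` (k/n), `z`, `p_value`.
#' @export
one_sample_proportion_test <- function(k, n, p0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("n must be a positive count")
  if (k < 0 || k > n) abort("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly between 0 and 1")
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  tibble(estimate = k / n, z = z, p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Exact two-library count-ratio test
#'
#' Conditional binomial comparison of one tile's counts in two libraries:
#' given the tile total `case + control`, the case count is binomial with
#' success probability `size_factor / (1 + size_factor)` under the null of
#' equal per-library rates, where `size_factor` is the case:control library
#' size ratio. Two-sided p sums all outcomes whose point probability does
#' not exceed that of the observation. Tiles with both counts zero get
#' p = 1 by convention. Vectorised over tiles.
#'
#' @param case,control Non-negative integer count vectors (recycled).
#' @param size_factor Case:control library-size ratio (scalar or vector).
#' @return Numeric vector of two-sided p-values.
#' @export
count_ratio_test <- function(case, control, size_factor = 1) {
  if (any(case < 0) || any(control < 0)) abort("counts must be non-negative")
  n <- length(case <- as.numeric(case))
  control <- rep_len(as.numeric(control), n)
  p0 <- rep_len(size_factor / (1 + size_factor), n)
  tot <- case + control
  vapply(seq_len(n), function(i) {
    if (tot[i] == 0) return(1)
    d <- dbinom(0:tot[i], tot[i], p0[i])
    min(1, sum(d[d <= d[case[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
}
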