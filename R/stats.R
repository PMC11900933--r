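# Rank-based two-group statistics and correlation layer.

#' Median and type-7 quartiles of a sample
#'
#' Summaries follow the median \[25th; 75th percentile\] convention with
#' type-7 (linear interpolation) quantiles, R's default.
#'
#' @param values Numeric vector, at least one finite value; `NA`s dropped.
#' @return A tibble with `n`, `median`, `q25`, `q75`.
#' @export
#' @examples
#' summarize_group(c(1, 2, 3, 4))
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("`values` must contain at least one finite value.")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  tibble::tibble(n = length(values), median = q[2], q25 = q[1], q75 = q[3])
}

#' Render a p-value the way clinical tables print it
#'
#' `"ns"` for p >= 0.05, `"<0.001"` below that threshold, otherwise
#' `"=0.0xx"` with three decimals.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p >= 0.05 ~ "ns",
    p < 0.001 ~ "<0.001",
    TRUE ~ sprintf("=%.3f", p)
  )
}

#' Unpaired two-group rank-sum (Mann-Whitney) test
#'
#' Two-sided Wilcoxon rank-sum test between two independent samples, the
#' group-comparison test for continuous variables. The exact null
#' distribution is used when the pooled size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie-variance and continuity
#' corrections. Group summaries use type-7 quartiles.
#'
#' @param values_a,values_b Numeric vectors with at least 2 finite values
#'   each (`NA`s dropped with a count kept in the result).
#' @param exact_max Pooled-size threshold for the exact distribution.
#' @return A one-row tibble (`comparison_result`): per-group median/quartiles,
#'   `statistic` (Mann-Whitney U for group A), `p_value`, `test_name`,
#'   `method` (`"exact"`/`"normal_approx"`), `n_missing`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(10, 11))
rank_sum_test <- function(values_a, values_b, exact_max = 20) {
  n_missing <- sum(!is.finite(values_a)) + sum(!is.finite(values_b))
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 finite values.")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= exact_max && !has_ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  sa <- summarize_group(a)
  sb <- summarize_group(b)
  tibble::tibble(
    n_a = sa$n, median_a = sa$median, q25_a = sa$q25, q75_a = sa$q75,
    n_b = sb$n, median_b = sb$median, q25_b = sb$q25, q75_b = sb$q75,
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    test_name = "Mann-Whitney rank-sum",
    method = if (exact) "exact" else "normal_approx",
    n_missing = n_missing
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' For genuinely paired measurements (equal length, same subjects). Provided
#' separately from [rank_sum_test()], which is the appropriate test for two
#' independent groups.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A one-row tibble with `statistic`, `p_value`, `test_name`, `n`.
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y)) abort("Paired vectors must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) abort("Need at least 2 complete pairs.")
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    test_name = "Wilcoxon signed-rank (paired)", n = length(x)
  )
}

#' Pearson chi-squared test on a contingency table
#'
#' Chi-squared test of independence without Yates continuity correction by
#' default. Warns when any expected count is below 5.
#'
#' @param table A matrix of non-negative integer counts (2 x k or larger),
#'   or a data frame coercible to one.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `test_name`,
#'   `min_expected`.
#' @export
#' @examples
#' chi_squared_test(matrix(c(19, 11, 17, 13), nrow = 2))
chi_squared_test <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    abort("`table` must contain non-negative integer counts.")
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("`table` must be at least 2x2.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Zero row or column marginal: the chi-squared test is undefined.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  min_exp <- min(ct$expected)
  if (min_exp < 5) {
    warn(sprintf("Minimum expected count is %.2f (< 5); the chi-squared approximation may be poor.", min_exp))
  }
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    test_name = if (correct) "Chi-squared (Yates)" else "Chi-squared",
    min_expected = min_exp
  )
}

# Spearman rho as the Pearson correlation of mid-ranks.
spearman_rho <- function(x, y) {
  cor(rank(x), rank(y))
}

# Exact two-sided permutation p-value for Spearman rho: enumerate all n!
# orderings of y against fixed x (mid-ranks throughout), count |rho| at least
# as extreme as observed. Feasible for n <= 8 (8! = 40320).
spearman_exact_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  perms <- permutations_of(n)
  obs <- cor(rx, ry)
  rho_all <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rho_all) >= abs(obs) - 1e-12)
}

# All permutations of 1..n as a matrix (n! rows); recursive, n <= 8 intended.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-sided p-value is computed by full permutation enumeration for
#' n <= `exact_max` (default 8) and by the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom otherwise.
#' A constant input vector leaves rho undefined (`NA` with flag).
#'
#' @param x,y Paired numeric vectors, length >= 3 after removing incomplete
#'   pairs.
#' @param exact_max Largest n for which the permutation null is enumerated.
#' @return A one-row tibble with `rho`, `p_value`, `n`, `method`, `flag`.
#' @export
#' @examples
#' spearman_correlation(1:6, c(2, 1, 4, 3, 6, 5))
spearman_correlation <- function(x, y, exact_max = 8) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = NA_character_, flag = "constant_input"))
  }
  rho <- spearman_rho(x, y)
  if (n <= exact_max) {
    p <- spearman_exact_p(x, y)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(2 * pt(-abs(tstat), df = n - 2), 1)
    method <- "t_approx"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method, flag = "ok")
}
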