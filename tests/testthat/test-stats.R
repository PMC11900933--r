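test_that("group summaries use type-7 quantiles with median between quartiles", {
  s <- summarize_group(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q25, s$q75), c(3, 2, 4))
  s4 <- summarize_group(c(1, 2, 3, 4))
  expect_equal(c(s4$median, s4$q25, s4$q75), c(2.5, 1.75, 3.25))
  sv <- summarize_group(7)
  expect_equal(c(sv$median, sv$q25, sv$q75), c(7, 7, 7))
  set.seed(9)
  for (i in 1:20) {
    s <- summarize_group(rnorm(sample(2:50, 1)))
    expect_true(s$q25 <= s$median && s$median <= s$q75)
  }
  expect_error(summarize_group(NA_real_), "finite")
})

test_that("rank-sum test: symmetry, small exact case, and quartile fill", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  r <- rank_sum_test(c(1, 2), c(10, 11))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_identical(r$method, "exact")
  expect_equal(r$median_a, 1.5)
  expect_equal(c(r$q25_b, r$q75_b), c(10.25, 10.75))
  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")
})

test_that("exact rank-sum p equals brute-force enumeration (8 vs 8 and random splits)", {
  set.seed(101)
  a <- sample(1000, 8); b <- sample(2000, 8) + 0.5
  expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_p(a, b),
               tolerance = 1e-12)
  for (i in 1:60) {
    na <- sample(2:6, 1); nb <- sample(2:(12 - na), 1)
    x <- sample(10000, na + nb) # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30) + 1
  r <- rank_sum_test(x, y)
  expect_identical(r$method, "normal_approx")
  expect_lt(r$p_value, 0.05)
  tied <- rank_sum_test(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_identical(tied$method, "normal_approx")
  expect_true(tied$p_value >= 0 && tied$p_value <= 1)
})

test_that("chi-squared test matches the 2x2 closed form and handles edge cases", {
  flat <- chi_squared_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  sex_split <- chi_squared_test(matrix(c(19, 11, 17, 13), nrow = 2))
  expect_lt(sex_split$statistic, 1)
  expect_gt(sex_split$p_value, 0.05)
  expect_identical(format_p_value(sex_split$p_value), "ns")

  set.seed(13)
  for (i in 1:20) {
    m <- matrix(sample(5:40, 4, replace = TRUE), 2)
    expect_equal(suppressWarnings(chi_squared_test(m))$statistic,
                 oracle_chisq_2x2(m), tolerance = 1e-12)
    # invariance under row/column permutation
    expect_equal(suppressWarnings(chi_squared_test(m[2:1, ]))$statistic,
                 suppressWarnings(chi_squared_test(m[, 2:1]))$statistic,
                 tolerance = 1e-12)
  }
  expect_error(chi_squared_test(matrix(c(0, 0, 5, 6), 2)), "marginal")
  expect_error(chi_squared_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  expect_warning(chi_squared_test(matrix(c(2, 3, 4, 5), 2)), "expected")
})

test_that("Yates correction is available behind a flag", {
  m <- matrix(c(12, 5, 7, 14), 2)
  expect_lt(suppressWarnings(chi_squared_test(m, correct = TRUE))$statistic,
            suppressWarnings(chi_squared_test(m))$statistic)
})

test_that("Spearman: monotone data, tied hand computation, exact enumeration", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)

  # 6-point tied data: x ranks (1.5, 1.5, 3, 4, 5.5, 5.5),
  # y = (2, 1, 3, 3, 5, 6) -> y ranks (2, 1, 3.5, 3.5, 5, 6);
  # Pearson correlation of these mid-ranks, hand-computed:
  x <- c(10, 10, 20, 30, 40, 40)
  y <- c(2, 1, 3, 3, 5, 6)
  rx <- c(1.5, 1.5, 3, 4, 5.5, 5.5); ry <- c(2, 1, 3.5, 3.5, 5, 6)
  hand_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_correlation(x, y)$rho, hand_rho, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    a <- sample(500, n); b <- sample(500, n)
    mine <- spearman_correlation(a, b)
    expect_identical(mine$method, "exact_permutation")
    ref <- cor.test(a, b, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- spearman_correlation(x, y)$rho
    expect_equal(spearman_correlation(exp(x), y)$rho, r0)
    expect_equal(spearman_correlation(x, y^3)$rho, r0)
    expect_equal(spearman_correlation(-x, y)$rho, -r0)
  }
})

test_that("Spearman handles large n via t approximation and flags constants", {
  set.seed(41)
  x <- rnorm(50); y <- x + rnorm(50)
  r <- spearman_correlation(x, y)
  expect_identical(r$method, "t_approx")
  expect_lt(r$p_value, 0.001)
  cst <- spearman_correlation(rep(1, 5), 1:5)
  expect_true(is.na(cst$rho))
  expect_identical(cst$flag, "constant_input")
  expect_error(spearman_correlation(1:3, 1:4), "paired")
})

test_that("paired signed-rank test is available for paired designs", {
  set.seed(19)
  x <- rnorm(15)
  r <- signed_rank_test(x, x + rnorm(15, mean = 2))
  expect_lt(r$p_value, 0.01)
  expect_error(signed_rank_test(1:3, 1:4), "equal length")
})

test_that("p-values render in the clinical display convention", {
  expect_identical(format_p_value(c(0.8, 0.05, 0.049, 0.0101, 0.001, 0.0009, NA)),
                   c("ns", "ns", "=0.049", "=0.010", "=0.001", "<0.001", NA))
})

test_that("build_table1 flags injected shifts and is null on copied groups", {
  set.seed(23)
  n <- 40
  d <- tibble::tibble(
    sample_id = as.character(1:(2 * n)),
    group = rep(c("A", "B"), each = n),
    shifted = c(rnorm(n), rnorm(n) + 5),
    null_var = rnorm(2 * n),
    flag = rep(c("yes", "no"), n)
  )
  t1 <- build_table1(d, categorical_vars = "flag")
  expect_s3_class(t1, "table_one")
  expect_identical(t1$p_display[t1$variable == "shifted"], "<0.001")
  expect_gt(t1$p_value[t1$variable == "null_var"], 0.05)
  expect_true(all(t1$q25_a[t1$type == "continuous"] <=
                    t1$median_a[t1$type == "continuous"]))

  copied <- tibble::tibble(
    group = rep(c("A", "B"), each = 10),
    v = rep(rnorm(10), 2)
  )
  t2 <- build_table1(copied)
  expect_gt(t2$p_value[t2$variable == "v"], 0.95)

  d$empty <- NA_real_
  expect_warning(build_table1(d, continuous_vars = c("shifted", "empty")),
                 "skipped")
  expect_error(build_table1(dplyr::mutate(d, group = "A")), "two groups")
})

test_that("table_one tidiers and autoplot work", {
  set.seed(29)
  d <- tibble::tibble(group = rep(c("A", "B"), each = 15),
                      v1 = rnorm(30), v2 = c(rnorm(15), rnorm(15) + 3))
  t1 <- build_table1(d)
  expect_s3_class(tidy(t1), "tbl_df")
  expect_equal(glance(t1)$n_variables, 2)
  expect_s3_class(autoplot(t1), "ggplot")
})
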