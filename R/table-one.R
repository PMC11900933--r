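# Table-1-style two-group comparison report.

#' Build a two-group "Table 1" comparison report
#'
#' For each continuous variable: per-group median \[q25; q75\] (type-7) and a
#' two-sided Mann-Whitney rank-sum p-value. For each categorical variable: a
#' 2 x k count split per group and a Pearson chi-squared p-value. P-values
#' are rendered `"ns"` / `"=0.0xx"` / `"<0.001"`; the raw value is kept in
#' `p_value`.
#'
#' @param data Cohort data frame.
#' @param group_col Name of the two-level grouping column.
#' @param continuous_vars,categorical_vars Character vectors of column names.
#'   By default every numeric column except `group_col` and `sample_id` is
#'   treated as continuous, and every logical/character/factor column as
#'   categorical. 0/1-coded numeric flags should be passed explicitly in
#'   `categorical_vars`.
#' @param digits Decimals used in the rendered `summary_a`/`summary_b`
#'   strings (value columns keep full precision).
#' @return A tibble of class `table_one`, one row per variable, with per-group
#'   summaries, `statistic`, `p_value`, `p_display` and `test_name`. Variables
#'   with fewer than 2 values in a group are skipped with a warning.
#' @export
build_table1 <- function(data, group_col = "group",
                         continuous_vars = NULL, categorical_vars = NULL,
                         digits = 1) {
  stopifnot(is.data.frame(data))
  if (!group_col %in% names(data)) {
    abort(paste0("Grouping column `", group_col, "` not found."))
  }
  g <- as.character(data[[group_col]])
  levels <- unique(g[!is.na(g)])
  if (length(levels) != 2L) {
    abort("`build_table1()` needs exactly two groups.")
  }
  la <- levels[1]; lb <- levels[2]

  if (is.null(continuous_vars)) {
    continuous_vars <- names(data)[vapply(data, is.numeric, logical(1))]
    continuous_vars <- setdiff(continuous_vars,
                               c(group_col, "sample_id", categorical_vars))
  }
  if (is.null(categorical_vars)) {
    categorical_vars <- names(data)[vapply(
      data, function(x) is.logical(x) || is.character(x) || is.factor(x),
      logical(1)
    )]
    categorical_vars <- setdiff(categorical_vars, c(group_col, "sample_id"))
  }

  fmt <- function(m, q1, q3) {
    sprintf(paste0("%.", digits, "f [%.", digits, "f; %.", digits, "f]"),
            m, q1, q3)
  }

  rows <- list()
  for (v in continuous_vars) {
    va <- data[[v]][g == la]
    vb <- data[[v]][g == lb]
    if (sum(is.finite(va)) < 2 || sum(is.finite(vb)) < 2) {
      warn(paste0("Variable `", v, "` skipped: fewer than 2 values in a group."))
      next
    }
    res <- rank_sum_test(va, vb)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, type = "continuous",
      summary_a = fmt(res$median_a, res$q25_a, res$q75_a),
      summary_b = fmt(res$median_b, res$q25_b, res$q75_b),
      median_a = res$median_a, q25_a = res$q25_a, q75_a = res$q75_a,
      median_b = res$median_b, q25_b = res$q25_b, q75_b = res$q75_b,
      statistic = res$statistic, p_value = res$p_value,
      test_name = res$test_name
    )
  }
  for (v in categorical_vars) {
    keep <- !is.na(g) & !is.na(data[[v]])
    if (!any(keep)) {
      warn(paste0("Variable `", v, "` skipped: no complete observations."))
      next
    }
    tab <- table(g[keep], as.character(data[[v]][keep]))
    if (nrow(tab) < 2 || ncol(tab) < 2 ||
        any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warn(paste0("Variable `", v, "` skipped: degenerate contingency table."))
      next
    }
    res <- suppressWarnings(chi_squared_test(unclass(tab)))
    split_str <- function(lv) paste(tab[lv, ], collapse = "/")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, type = "categorical",
      summary_a = split_str(la), summary_b = split_str(lb),
      median_a = NA_real_, q25_a = NA_real_, q75_a = NA_real_,
      median_b = NA_real_, q25_b = NA_real_, q75_b = NA_real_,
      statistic = res$statistic, p_value = res$p_value,
      test_name = res$test_name
    )
  }
  if (!length(rows)) abort("No testable variables found.")
  out <- dplyr::bind_rows(rows)
  out$p_display <- format_p_value(out$p_value)
  out <- out[, c("variable", "type", "summary_a", "summary_b", "statistic",
                 "p_value", "p_display", "test_name", "median_a", "q25_a",
                 "q75_a", "median_b", "q25_b", "q75_b")]
  structure(out, class = c("table_one", class(out)),
            groups = c(a = la, b = lb))
}

#' @export
print.table_one <- function(x, ...) {
  grp <- attr(x, "groups")
  cat(sprintf("Group comparison: %s (A) vs %s (B), %d variables\n\n",
              grp[["a"]], grp[["b"]], nrow(x)))
  shown <- as.data.frame(x[, c("variable", "summary_a", "summary_b", "p_display")])
  names(shown) <- c("variable", grp[["a"]], grp[["b"]], "p")
  print(shown, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.table_one <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.table_one <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
    n_continuous = sum(x$type == "continuous"),
    n_categorical = sum(x$type == "categorical")
  )
}

#' @describeIn build_table1 Bar chart of -log10 p-values per variable.
#' @param object A `table_one` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.table_one <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  d$variable <- stats::reorder(d$variable, -log10(d$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable,
                                  y = -log10(.data$p_value),
                                  fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Two-group comparisons") +
    ggplot2::theme_minimal()
}
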