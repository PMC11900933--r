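# ggplot2 figure helpers for scored cohorts.

#' Scatter of epigenetic (or vascular) age against chronological age
#'
#' One panel per group, identity line for reference: points below the line
#' are epigenetically younger than their calendar age.
#'
#' @param data A scored cohort (e.g. `run_pipeline(...)$subjects`).
#' @param y Name of the y variable (default `"epigenetic_age"`).
#' @param x Name of the x variable (default `"age_years"`).
#' @param group_col Grouping column used for facets/colour.
#' @return A ggplot object.
#' @export
plot_age_scatter <- function(data, y = "epigenetic_age", x = "age_years",
                             group_col = "group") {
  stopifnot(is.data.frame(data), all(c(x, y) %in% names(data)))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]]))
  if (group_col %in% names(data)) {
    p <- p + ggplot2::aes(colour = .data[[group_col]]) +
      ggplot2::facet_wrap(ggplot2::vars(.data[[group_col]]))
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "Chronological age (years)",
                  y = gsub("_", " ", y)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Boxplots of the age measures by group
#'
#' @param data A scored cohort table.
#' @param vars Variables to show (defaults to the age measures present).
#' @param group_col Grouping column.
#' @return A ggplot object.
#' @export
plot_group_ages <- function(data,
                            vars = c("age_years", "epigenetic_age",
                                     "vascular_age", "age_acceleration",
                                     "vascular_ageing"),
                            group_col = "group") {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  vars <- intersect(vars, names(data))
  if (!length(vars)) abort("None of the requested variables are present.")
  long <- tidyr::pivot_longer(
    data[, c(group_col, vars)], dplyr::all_of(vars),
    names_to = "measure", values_to = "years"
  )
  long$measure <- factor(long$measure, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group_col]], y = .data$years,
                                     fill = .data[[group_col]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Years") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @describeIn run_pipeline Plot a cohort report: `"correlation"` (epigenetic
#'   vs chronological age scatter), `"ages"` or `"acceleration"` (group
#'   boxplots).
#' @param object A `cohort_report`.
#' @param type Which figure to draw.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object,
                                   type = c("correlation", "ages",
                                            "acceleration"), ...) {
  type <- match.arg(type)
  switch(
    type,
    correlation = plot_age_scatter(object$subjects),
    ages = plot_group_ages(object$subjects,
                           vars = c("age_years", "epigenetic_age", "vascular_age")),
    acceleration = plot_group_ages(object$subjects,
                                   vars = c("age_acceleration", "vascular_ageing"))
  )
}
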