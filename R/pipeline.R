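# Full analysis pipeline: clock -> Framingham -> HOMA-IR -> group statistics.

#' Run the full case-control ageing analysis on a cohort
#'
#' Chains every stage the package implements on one cohort table and
#' collects the study-style outputs:
#' per-subject epigenetic age, age acceleration, 10-year Framingham risk,
#' vascular age, vascular ageing and HOMA-IR; a Table-1-style two-group
#' comparison; within-group Spearman correlations of epigenetic age and age
#' acceleration against every numeric covariate; within-group correlations
#' of epigenetic age with chronological and vascular age; and the two-group
#' contrasts of the four age measures. A stage whose input columns are
#' missing is skipped with a log entry, never an error.
#'
#' @param cohort A cohort data frame or a path readable by [read_cohort()].
#' @param group_col Two-level grouping column name.
#' @param model [clock_model()] for the clock stage.
#' @param ref [frs_reference()] for the vascular-age inversion.
#' @param conversion Glucose conversion for HOMA-IR, see [add_homa_ir()].
#' @return A list of class `cohort_report`: `subjects` (augmented tibble),
#'   `table1` ([build_table1()] output), `correlations`,
#'   `age_correlations`, `group_contrasts` (tibbles), and `log` (character).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_sim_config(), seed = 1)
#' rep <- run_pipeline(cohort)
#' rep$table1
run_pipeline <- function(cohort, group_col = "group", model = clock_model(),
                         ref = frs_reference(),
                         conversion = c("standard", "rounded")) {
  conversion <- match.arg(conversion)
  if (is.character(cohort) && length(cohort) == 1L) cohort <- read_cohort(cohort)
  stopifnot(is.data.frame(cohort))
  subjects <- tibble::as_tibble(cohort)
  log <- character(0)
  note <- function(msg) {
    log <<- c(log, msg)
    inform(msg)
  }

  has_meth <- all(clock_sites() %in% names(subjects))
  frs_cols <- c("age_years", "sex", "sbp_mmhg", "htn_treated", "smoker",
                "diabetes", "tc_mgdl", "hdl_mgdl")
  has_frs <- all(frs_cols %in% names(subjects))
  has_homa <- "insulin_uiu_ml" %in% names(subjects) &&
    any(c("glucose_mgdl", "glucose_mmol") %in% names(subjects))

  if (has_meth) {
    subjects <- add_epigenetic_age(subjects, model = model)
    log <- c(log, "clock: epigenetic age and age acceleration computed")
  } else {
    note("clock: skipped (methylation columns missing)")
  }
  if (has_frs) {
    subjects <- add_framingham(subjects, ref = ref, quiet = TRUE)
    log <- c(log, "framingham: 10-year risk, vascular age and vascular ageing computed")
  } else {
    note(paste0("framingham: skipped (missing ",
                paste(setdiff(frs_cols, names(subjects)), collapse = ", "), ")"))
  }
  if (has_homa) {
    subjects <- add_homa_ir(subjects, conversion = conversion)
    log <- c(log, "biochem: HOMA-IR computed")
  } else {
    note("biochem: HOMA-IR skipped (insulin/glucose columns missing)")
  }

  two_groups <- group_col %in% names(subjects) &&
    length(unique(subjects[[group_col]])) == 2L

  table1 <- NULL
  correlations <- NULL
  age_correlations <- NULL
  group_contrasts <- NULL

  if (!two_groups) {
    note("stats: group comparisons skipped (need exactly two groups)")
  } else {
    categorical <- intersect(c("sex", "smoker", "diabetes", "htn_treated"),
                             names(subjects))
    continuous <- setdiff(
      names(subjects)[vapply(subjects, is.numeric, logical(1))],
      c(categorical, "sample_id")
    )
    table1 <- suppressWarnings(build_table1(
      subjects, group_col = group_col,
      continuous_vars = continuous, categorical_vars = categorical
    ))
    log <- c(log, "stats: Table-1-style group comparison computed")

    groups <- unique(subjects[[group_col]])
    targets <- intersect(c("epigenetic_age", "age_acceleration"), names(subjects))
    covars <- setdiff(continuous, targets)
    if (length(targets)) {
      sweep <- tidyr::expand_grid(group = groups, outcome = targets,
                                  covariate = covars)
      correlations <- dplyr::bind_cols(sweep, purrr::pmap_dfr(
        sweep, function(group, outcome, covariate) {
          d <- subjects[subjects[[group_col]] == group, ]
          x <- d[[outcome]]; y <- d[[covariate]]
          if (sum(is.finite(x) & is.finite(y)) < 3) {
            return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                                  n = sum(is.finite(x) & is.finite(y)),
                                  method = NA_character_, flag = "too_few"))
          }
          spearman_correlation(x, y)
        }
      ))
      correlations$p_display <- format_p_value(correlations$p_value)
      log <- c(log, "stats: within-group correlation sweep computed")

      pairs <- tibble::tibble(
        x = c("age_years", "vascular_age"),
        y = c("epigenetic_age", "epigenetic_age")
      )
      pairs <- pairs[pairs$x %in% names(subjects) & pairs$y %in% names(subjects), ]
      if (nrow(pairs)) {
        grid <- tidyr::expand_grid(group = groups, pairs)
        age_correlations <- dplyr::bind_cols(grid, purrr::pmap_dfr(
          grid, function(group, x, y) {
            d <- subjects[subjects[[group_col]] == group, ]
            spearman_correlation(d[[x]], d[[y]])
          }
        ))
        age_correlations$p_display <- format_p_value(age_correlations$p_value)
        log <- c(log, "stats: within-group age correlations computed")
      }

      contrast_vars <- intersect(
        c("age_years", "epigenetic_age", "age_acceleration",
          "vascular_age", "vascular_ageing"),
        names(subjects)
      )
      group_contrasts <- purrr::map_dfr(contrast_vars, function(v) {
        va <- subjects[[v]][subjects[[group_col]] == groups[1]]
        vb <- subjects[[v]][subjects[[group_col]] == groups[2]]
        if (sum(is.finite(va)) < 2 || sum(is.finite(vb)) < 2) return(NULL)
        dplyr::bind_cols(tibble::tibble(variable = v), rank_sum_test(va, vb))
      })
      if (!is.null(group_contrasts) && nrow(group_contrasts)) {
        group_contrasts$p_display <- format_p_value(group_contrasts$p_value)
      }
      log <- c(log, "stats: group contrasts of age measures computed")
    }
  }

  structure(
    list(subjects = subjects, table1 = table1, correlations = correlations,
         age_correlations = age_correlations, group_contrasts = group_contrasts,
         log = log),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort ageing analysis report\n")
  cat(sprintf("  subjects: %d\n", nrow(x$subjects)))
  for (el in c("table1", "correlations", "age_correlations", "group_contrasts")) {
    cat(sprintf("  %-17s %s\n", el,
                if (is.null(x[[el]])) "skipped" else sprintf("%d rows", nrow(x[[el]]))))
  }
  cat("Stages:\n")
  cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  if (is.null(x$table1)) abort("This report has no group-comparison table.")
  tidy(x$table1)
}

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    n_groups = length(unique(x$subjects$group %||% character(0))),
    n_table1_vars = if (is.null(x$table1)) 0L else nrow(x$table1),
    n_correlations = if (is.null(x$correlations)) 0L else nrow(x$correlations),
    n_stages = length(x$log)
  )
}
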