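#' Canonical CpG site names of the five-site blood methylation clock
#'
#' The clock reads percent methylation at one CpG each in ELOVL2 (position C7
#' of the pyrosequencing amplicon), C1orf132/MIR29B2C (C1), TRIM59 (C7),
#' KLF14 (C1) and FHL2 (C2). Column names are `<gene>_<position>`.
#'
#' @return Character vector of the five canonical column names.
#' @export
#' @examples
#' clock_sites()
clock_sites <- function() {
  c("ELOVL2_C7", "C1orf132_C1", "TRIM59_C7", "KLF14_C1", "FHL2_C2")
}

# Accepted aliases -> canonical names. C1orf132 is also annotated as MIR29B2C.
.site_aliases <- c(
  ELOVL2_C7    = "ELOVL2_C7",
  C1orf132_C1  = "C1orf132_C1",
  MIR29B2C_C1  = "C1orf132_C1",
  C1ORF132_C1  = "C1orf132_C1",
  TRIM59_C7    = "TRIM59_C7",
  KLF14_C1     = "KLF14_C1",
  FHL2_C2      = "FHL2_C2",
  ELOVL2       = "ELOVL2_C7",
  C1orf132     = "C1orf132_C1",
  C1ORF132     = "C1orf132_C1",
  MIR29B2C     = "C1orf132_C1",
  TRIM59       = "TRIM59_C7",
  KLF14        = "KLF14_C1",
  FHL2         = "FHL2_C2"
)

#' Resolve methylation column names to canonical clock site names
#'
#' @param x Character vector of column or element names.
#' @return Named character vector mapping each recognised input name to its
#'   canonical site name; unrecognised names are dropped.
#' @keywords internal
resolve_site_names <- function(x) {
  hit <- .site_aliases[match(x, names(.site_aliases))]
  setNames(hit[!is.na(hit)], x[!is.na(hit)])
}

#' The five-CpG linear epigenetic age clock
#'
#' Constructs the linear model `age = intercept + sum(coef_site * percent
#' methylation at site)`. The default coefficients are the published blood
#' pyrosequencing clock used throughout this package: methylation is expressed
#' in percent (0-100) and predicted age in years, so each coefficient is years
#' per percentage point. C1orf132 is the only site where methylation falls
#' with age, hence the sole negative coefficient.
#'
#' @param intercept Model intercept in years.
#' @param coefficients Named numeric vector of length 5; names must resolve to
#'   [clock_sites()].
#' @return An object of class `clock_model`.
#' @export
#' @examples
#' clock_model()
#' tidy(clock_model())
clock_model <- function(intercept = 3.26847784751817,
                        coefficients = c(
                          ELOVL2_C7   =  0.465445549010653,
                          C1orf132_C1 = -0.355450171437202,
                          TRIM59_C7   =  0.306488541137007,
                          KLF14_C1    =  0.832684435238792,
                          FHL2_C2     =  0.237081243617191
                        )) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    abort("`intercept` must be a single finite number.")
  }
  if (length(coefficients) != 5L || is.null(names(coefficients))) {
    abort("`coefficients` must be a named numeric vector of length 5.")
  }
  canon <- resolve_site_names(names(coefficients))
  if (length(canon) != 5L || anyDuplicated(canon)) {
    bad <- setdiff(names(coefficients), names(canon))
    abort(paste0(
      "Unknown clock site name(s): ", paste(bad, collapse = ", "),
      ". Expected names resolving to: ", paste(clock_sites(), collapse = ", ")
    ))
  }
  coefficients <- setNames(as.numeric(coefficients), unname(canon))[clock_sites()]
  if (!all(is.finite(coefficients))) abort("All clock coefficients must be finite.")
  structure(
    list(intercept = intercept, coefficients = coefficients),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Five-CpG linear epigenetic age clock\n")
  cat(sprintf("  intercept: %.14f years\n", x$intercept))
  for (s in clock_sites()) {
    cat(sprintf("  %-12s %+.14f years / %% methylation\n", s, x$coefficients[[s]]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clock_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", clock_sites()),
    estimate = c(x$intercept, unname(x$coefficients[clock_sites()]))
  )
}

#' @exportS3Method generics::glance
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$coefficients),
    intercept = x$intercept,
    n_negative_coef = sum(x$coefficients < 0)
  )
}

# Validate a numeric methylation matrix (rows = samples, canonical columns),
# raising errors that name the offending site. Values in (0, 1] look like
# fractions rather than percentages; `strict_percent` upgrades that warning to
# an error.
check_methylation <- function(m, strict_percent = FALSE) {
  for (s in clock_sites()) {
    v <- m[, s]
    if (anyNA(v)) {
      abort(paste0("Missing methylation value at site ", s, "."))
    }
    if (any(!is.finite(v))) {
      abort(paste0("Non-finite methylation value at site ", s, "."))
    }
    if (any(v < 0 | v > 100)) {
      abort(paste0("Methylation at site ", s,
                   " outside [0, 100] percent: values must be percentages."))
    }
  }
  # A profile whose five sites all sit in [0, 1] (with at least one nonzero)
  # almost certainly carries fractions, not percentages.
  frac_like <- apply(m, 1, function(r) all(r <= 1) && any(r > 0))
  if (any(frac_like)) {
    msg <- paste0(
      "Some profiles have all methylation values in (0, 1]; inputs are ",
      "expected in percent (0-100), not fractions. Multiply by 100 if these ",
      "are fractions."
    )
    if (strict_percent) abort(msg) else warn(msg)
  }
  invisible(m)
}

# Coerce a profile (named vector, list, or data frame with site columns) to a
# numeric matrix with canonical columns.
as_meth_matrix <- function(profile) {
  if (is.data.frame(profile)) {
    canon <- resolve_site_names(names(profile))
    missing <- setdiff(clock_sites(), unname(canon))
    if (length(missing)) {
      abort(paste0("Missing methylation column(s): ", paste(missing, collapse = ", ")))
    }
    if (anyDuplicated(unname(canon))) {
      abort("Multiple columns resolve to the same clock site.")
    }
    m <- as.matrix(profile[names(canon)])
    if (!is.numeric(m)) abort("Methylation columns must be numeric.")
    colnames(m) <- unname(canon)
    m[, clock_sites(), drop = FALSE]
  } else if (is.numeric(profile) || is.list(profile)) {
    v <- unlist(profile)
    if (is.null(names(v))) abort("A methylation profile must have site names.")
    canon <- resolve_site_names(names(v))
    unknown <- setdiff(names(v), names(canon))
    if (length(unknown)) {
      abort(paste0("Unknown methylation site name(s): ",
                   paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(clock_sites(), unname(canon))
    if (length(missing)) {
      abort(paste0("Missing methylation site(s): ", paste(missing, collapse = ", ")))
    }
    m <- matrix(as.numeric(v), nrow = 1, dimnames = list(NULL, unname(canon)))
    m[, clock_sites(), drop = FALSE]
  } else {
    abort("`profile` must be a named numeric vector, list, or data frame.")
  }
}

#' Predict epigenetic age from five-CpG percent methylation
#'
#' Evaluates the linear clock on one or more methylation profiles. No clamping
#' is applied: for extreme inputs the linear model can return ages below zero,
#' which are returned as-is with a warning.
#'
#' @param profile A named numeric vector with the five site values, or a data
#'   frame with one column per site (one row per sample). Site names may use
#'   the aliases recognised by [resolve_site_names()], e.g. `MIR29B2C_C1` for
#'   `C1orf132_C1`. Values are percent methylation in \[0, 100\].
#' @param model A [clock_model()]; defaults to the published coefficients.
#' @param strict_percent If `TRUE`, values in (0, 1] (which look like
#'   fractions) are an error instead of a warning.
#' @return Numeric vector of predicted epigenetic ages in years, one per
#'   sample.
#' @export
#' @examples
#' predict_epigenetic_age(
#'   c(ELOVL2_C7 = 50, C1orf132_C1 = 40, TRIM59_C7 = 30,
#'     KLF14_C1 = 5, FHL2_C2 = 20)
#' )
predict_epigenetic_age <- function(profile, model = clock_model(),
                                   strict_percent = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  m <- as_meth_matrix(profile)
  check_methylation(m, strict_percent = strict_percent)
  age <- drop(model$intercept + m %*% model$coefficients[clock_sites()])
  if (any(age < 0)) {
    warn("Predicted epigenetic age below 0 years for some sample(s); the linear clock is unbounded and the raw value is returned.")
  }
  unname(age)
}

#' Age acceleration: epigenetic minus chronological age
#'
#' Negative values mean the methylation profile looks younger than the
#' calendar age.
#'
#' @param epigenetic_age,chronological_age Numeric vectors in years
#'   (recycled to common length).
#' @return `epigenetic_age - chronological_age`, in years.
#' @export
#' @examples
#' age_acceleration(24.4, 36.8)
age_acceleration <- function(epigenetic_age, chronological_age) {
  if (!is.numeric(epigenetic_age) || !is.numeric(chronological_age)) {
    abort("Both ages must be numeric.")
  }
  if (any(!is.finite(epigenetic_age)) || any(!is.finite(chronological_age))) {
    abort("Both ages must be finite.")
  }
  if (any(chronological_age <= 0)) {
    abort("`chronological_age` must be positive.")
  }
  epigenetic_age - chronological_age
}

#' Add epigenetic age (and acceleration) columns to a cohort table
#'
#' Data-frame-first wrapper around [predict_epigenetic_age()]: one row per
#' sample in, the same rows out (order preserved) with `epigenetic_age` and,
#' where chronological age is available, `age_acceleration` appended.
#'
#' @param data A data frame with a `sample_id` column and the five methylation
#'   columns (canonical names or aliases). If `age_col` is present,
#'   acceleration is filled; rows with missing age get `NA` acceleration.
#' @param model A [clock_model()].
#' @param age_col Name of the chronological age column (default `age_years`).
#' @param strict_percent See [predict_epigenetic_age()].
#' @return A tibble: `data` plus `epigenetic_age` (+ `age_acceleration`).
#' @export
add_epigenetic_age <- function(data, model = clock_model(),
                               age_col = "age_years",
                               strict_percent = FALSE) {
  stopifnot(is.data.frame(data))
  if ("sample_id" %in% names(data) && anyDuplicated(data$sample_id)) {
    abort("Duplicate sample_id in input.")
  }
  out <- tibble::as_tibble(data)
  if (nrow(out) == 0L) {
    out$epigenetic_age <- numeric(0)
    out$age_acceleration <- numeric(0)
    return(out)
  }
  out$epigenetic_age <- predict_epigenetic_age(
    data, model = model, strict_percent = strict_percent
  )
  if (age_col %in% names(out)) {
    age <- out[[age_col]]
    ok <- is.finite(age) & age > 0
    acc <- rep(NA_real_, nrow(out))
    acc[ok] <- out$epigenetic_age[ok] - age[ok]
    out$age_acceleration <- acc
  }
  out
}
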