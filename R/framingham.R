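# 2008 Framingham general-CVD risk and vascular age by risk-function
# inversion. The Cox-model constants live in a version-pinned CSV under
# inst/extdata so they can be audited independently of the code.

.frs_cache <- new.env(parent = emptyenv())

#' Coefficients of the 2008 Framingham general-CVD risk function
#'
#' Loads the sex-specific lipid-based Cox model constants (log-scale betas,
#' mean linear predictor, 10-year baseline survival) from the package's
#' version-pinned constants file. Values are transcribed from D'Agostino et
#' al., Circulation 2008.
#'
#' @param path Optional path to an alternative constants CSV with columns
#'   `sex,term,value` (comment lines start with `#`).
#' @return A named list with elements `female` and `male`, each a named
#'   numeric vector of model constants.
#' @export
frs_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.frs_cache$default)) return(.frs_cache$default)
    path <- system.file("extdata", "frs_general_cvd_2008.csv",
                        package = "epivasc", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("b_ln_age", "b_ln_tc", "b_ln_hdl", "b_ln_sbp_untreated",
            "b_ln_sbp_treated", "b_smoker", "b_diabetes", "lp_mean", "s0_10")
  out <- lapply(split(tab, tab$sex), function(d) setNames(d$value, d$term))
  for (sx in c("female", "male")) {
    if (is.null(out[[sx]]) || !all(need %in% names(out[[sx]]))) {
      abort(paste0("Corrupt FRS constants file: missing terms for sex '", sx, "'."))
    }
  }
  out <- out[c("female", "male")]
  if (cache) .frs_cache$default <- out
  out
}

#' Normal-risk-factor reference profile for vascular age
#'
#' Vascular ("heart") age is the age at which a same-sex person with all
#' modifiable risk factors at normal levels has the same predicted 10-year
#' CVD risk. The defaults are the normal levels used by the 2008 Framingham
#' heart-age construction: untreated SBP 125 mmHg, total cholesterol
#' 180 mg/dL, HDL 45 mg/dL, non-smoker, non-diabetic (both sexes).
#'
#' @param sbp Untreated systolic blood pressure, mmHg.
#' @param total_chol Total cholesterol, mg/dL.
#' @param hdl_chol HDL cholesterol, mg/dL.
#' @return An object of class `frs_reference`.
#' @export
frs_reference <- function(sbp = 125, total_chol = 180, hdl_chol = 45) {
  stopifnot(sbp > 0, total_chol > 0, hdl_chol > 0)
  structure(
    list(sbp = sbp, total_chol = total_chol, hdl_chol = hdl_chol,
         on_htn_treatment = FALSE, smoker = FALSE, diabetic = FALSE),
    class = "frs_reference"
  )
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep(NA_character_, length(s))
  out[s %in% c("f", "female", "w")] <- "female"
  out[s %in% c("m", "male")] <- "male"
  if (anyNA(out)) {
    abort(paste0("Unrecognised sex code(s): ",
                 paste(unique(sex[is.na(out)]), collapse = ", "),
                 " (expected F/M or female/male)."))
  }
  out
}

#' 10-year general cardiovascular disease risk (Framingham 2008)
#'
#' Sex-specific Cox-form risk `1 - S0(10)^exp(lp - lp_mean)` with the
#' lipid-based linear predictor on log-transformed age, total cholesterol,
#' HDL and SBP (treatment-specific SBP coefficient) plus smoking and diabetes
#' indicators. Vectorised over all arguments.
#'
#' @param age Age in years. The function was derived for ages 30-74; outside
#'   20-100 a warning is emitted and the value computed anyway.
#' @param sex `"F"`/`"M"` (or `female`/`male`), any mix.
#' @param sbp Systolic blood pressure, mmHg.
#' @param on_htn_treatment Logical (or 0/1): on antihypertensive treatment.
#' @param smoker Logical (or 0/1): current smoker.
#' @param diabetic Logical (or 0/1): diabetes mellitus.
#' @param total_chol Total cholesterol, mg/dL.
#' @param hdl_chol HDL cholesterol, mg/dL.
#' @param coef FRS constants as returned by [frs_coefficients()].
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' # Worked example from D'Agostino et al. (2008): ~10.5% risk
#' general_cvd_risk(61, "F", 124, FALSE, TRUE, FALSE, 180, 47)
general_cvd_risk <- function(age, sex, sbp, on_htn_treatment, smoker,
                             diabetic, total_chol, hdl_chol,
                             coef = frs_coefficients()) {
  n <- max(length(age), length(sex), length(sbp), length(on_htn_treatment),
           length(smoker), length(diabetic), length(total_chol), length(hdl_chol))
  age <- rep_len(as.numeric(age), n)
  sexn <- rep_len(normalize_sex(sex), n)
  sbp <- rep_len(as.numeric(sbp), n)
  trt <- rep_len(as.logical(on_htn_treatment), n)
  smk <- rep_len(as.logical(smoker), n)
  dm <- rep_len(as.logical(diabetic), n)
  tc <- rep_len(as.numeric(total_chol), n)
  hdl <- rep_len(as.numeric(hdl_chol), n)

  if (any(!is.finite(age)) || any(age <= 0)) abort("`age` must be finite and positive.")
  if (any(!is.finite(sbp)) || any(sbp <= 0)) abort("`sbp` must be finite and positive.")
  if (any(!is.finite(tc)) || any(tc <= 0)) abort("`total_chol` must be finite and positive.")
  if (any(!is.finite(hdl)) || any(hdl <= 0)) abort("`hdl_chol` must be finite and positive.")
  if (anyNA(trt) || anyNA(smk) || anyNA(dm)) abort("Treatment/smoking/diabetes flags must not be missing.")
  if (any(age < 20 | age > 100)) {
    warn("Some ages are outside 20-100 years; the Framingham function was derived for 30-74 and is extrapolated here.")
  }

  risk <- numeric(n)
  for (sx in c("female", "male")) {
    idx <- sexn == sx
    if (!any(idx)) next
    cf <- coef[[sx]]
    b_sbp <- ifelse(trt[idx], cf[["b_ln_sbp_treated"]], cf[["b_ln_sbp_untreated"]])
    lp <- cf[["b_ln_age"]] * log(age[idx]) +
      cf[["b_ln_tc"]] * log(tc[idx]) +
      cf[["b_ln_hdl"]] * log(hdl[idx]) +
      b_sbp * log(sbp[idx]) +
      cf[["b_smoker"]] * smk[idx] +
      cf[["b_diabetes"]] * dm[idx]
    risk[idx] <- 1 - cf[["s0_10"]] ^ exp(lp - cf[["lp_mean"]])
  }
  pmin(pmax(risk, 0), 1)
}

# Risk of the same-sex reference ("all normal") profile at candidate age(s).
reference_risk <- function(age, sex, ref = frs_reference(),
                           coef = frs_coefficients()) {
  suppressWarnings(general_cvd_risk(
    age = age, sex = sex, sbp = ref$sbp,
    on_htn_treatment = ref$on_htn_treatment, smoker = ref$smoker,
    diabetic = ref$diabetic, total_chol = ref$total_chol,
    hdl_chol = ref$hdl_chol, coef = coef
  ))
}

#' Vascular age by inversion of the Framingham risk function
#'
#' Finds, for each subject, the age at which a same-sex person with all risk
#' factors at the reference ("normal") levels has the same predicted 10-year
#' CVD risk. Because the reference risk is strictly increasing in age, the
#' equation is solved by root bracketing (bisection via [stats::uniroot()])
#' over ages 15-120. Risks beyond the bracket are clipped: a target above the
#' risk at 120 returns 120 with flag `"saturated"`, below the risk at 15
#' returns 15 with flag `"floored"`; otherwise the flag is `"ok"`.
#'
#' @inheritParams general_cvd_risk
#' @param ref Reference profile, see [frs_reference()].
#' @param lower,upper Search bracket for age, years.
#' @return A tibble with columns `vascular_age` (years) and `flag`.
#' @export
vascular_age <- function(age, sex, sbp, on_htn_treatment, smoker, diabetic,
                         total_chol, hdl_chol, ref = frs_reference(),
                         coef = frs_coefficients(),
                         lower = 15, upper = 120) {
  target <- general_cvd_risk(age, sex, sbp, on_htn_treatment, smoker,
                             diabetic, total_chol, hdl_chol, coef = coef)
  sexn <- rep_len(normalize_sex(sex), length(target))
  va <- numeric(length(target))
  flag <- character(length(target))
  for (sx in c("female", "male")) {
    idx <- which(sexn == sx)
    if (!length(idx)) next
    r_lo <- reference_risk(lower, sx, ref, coef)
    r_hi <- reference_risk(upper, sx, ref, coef)
    if (r_lo >= r_hi) {
      abort("Reference risk is not increasing over the age bracket; the FRS constants file is corrupted.")
    }
    for (i in idx) {
      tg <- target[[i]]
      if (tg <= r_lo) {
        va[i] <- lower; flag[i] <- "floored"
      } else if (tg >= r_hi) {
        va[i] <- upper; flag[i] <- "saturated"
      } else {
        root <- uniroot(
          function(a) reference_risk(a, sx, ref, coef) - tg,
          lower = lower, upper = upper, tol = 1e-10
        )
        va[i] <- root$root; flag[i] <- "ok"
      }
    }
  }
  tibble::tibble(vascular_age = va, flag = flag)
}

#' Vascular ageing: vascular minus chronological age
#'
#' @param va,chronological_age Numeric vectors in years.
#' @return `va - chronological_age`, signed, in years.
#' @export
#' @examples
#' vascular_ageing(51.5, 43.4)
vascular_ageing <- function(va, chronological_age) {
  if (any(!is.finite(va)) || any(!is.finite(chronological_age))) {
    abort("Both ages must be finite.")
  }
  va - chronological_age
}

#' Add Framingham risk, vascular age and vascular ageing to a cohort table
#'
#' Expects the canonical cohort columns `age_years`, `sex`, `sbp_mmhg`,
#' `htn_treated`, `smoker`, `diabetes`, `tc_mgdl`, `hdl_mgdl`. Rows with any
#' of these missing get `NA` results.
#'
#' @param data Cohort data frame.
#' @param ref Reference profile for the inversion, see [frs_reference()].
#' @param quiet Suppress the extrapolation warning for ages outside 20-100
#'   (the per-row flag column still records bracket saturation).
#' @return `data` as a tibble plus `frs_risk` (probability), `vascular_age`,
#'   `vascular_ageing` (years) and `frs_flag`.
#' @export
add_framingham <- function(data, ref = frs_reference(), quiet = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("age_years", "sex", "sbp_mmhg", "htn_treated", "smoker",
            "diabetes", "tc_mgdl", "hdl_mgdl")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Missing column(s) for Framingham stage: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$frs_risk <- NA_real_
  out$vascular_age <- NA_real_
  out$vascular_ageing <- NA_real_
  out$frs_flag <- NA_character_
  ok <- complete.cases(out[need]) & out$age_years > 0 & out$sbp_mmhg > 0 &
    out$tc_mgdl > 0 & out$hdl_mgdl > 0
  if (!any(ok)) return(out)
  compute <- function() {
    risk <- general_cvd_risk(
      out$age_years[ok], out$sex[ok], out$sbp_mmhg[ok], out$htn_treated[ok],
      out$smoker[ok], out$diabetes[ok], out$tc_mgdl[ok], out$hdl_mgdl[ok]
    )
    va <- vascular_age(
      out$age_years[ok], out$sex[ok], out$sbp_mmhg[ok], out$htn_treated[ok],
      out$smoker[ok], out$diabetes[ok], out$tc_mgdl[ok], out$hdl_mgdl[ok],
      ref = ref
    )
    list(risk = risk, va = va)
  }
  res <- if (quiet) suppressWarnings(compute()) else compute()
  out$frs_risk[ok] <- res$risk
  out$vascular_age[ok] <- res$va$vascular_age
  out$vascular_ageing[ok] <- res$va$vascular_age - out$age_years[ok]
  out$frs_flag[ok] <- res$va$flag
  out
}
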