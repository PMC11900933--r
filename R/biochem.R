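# Clinical-chemistry derived quantities.

#' HOMA-IR insulin resistance index
#'
#' `HOMA-IR = fasting insulin (uIU/mL) x fasting glucose (mmol/L) / 22.5`.
#' Glucose must already be in mmol/L; see [glucose_mgdl_to_mmol()].
#'
#' @param insulin Fasting insulin, uIU/mL (> 0).
#' @param glucose Fasting glucose, mmol/L (> 0).
#' @return Dimensionless index, vectorised.
#' @export
#' @examples
#' homa_ir(22.5, 1)    # 1
#' homa_ir(13.2, glucose_mgdl_to_mmol(101))
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose))) {
    abort("`insulin` and `glucose` must be finite.")
  }
  if (any(insulin <= 0)) abort("`insulin` must be positive (uIU/mL).")
  if (any(glucose <= 0)) abort("`glucose` must be positive (mmol/L).")
  insulin * glucose / 22.5
}

.glucose_factors <- c(standard = 0.0555, rounded = 0.06)

#' Convert glucose between mg/dL and mmol/L
#'
#' The default factor is the conventional 0.0555 mmol/L per mg/dL
#' (1/18.016 to three significant figures). `conversion = "rounded"` uses the
#' coarser 0.06 sometimes quoted in assay documentation, kept for
#' bit-compatibility with analyses that used it.
#'
#' @param x Glucose in mg/dL (or mmol/L for the inverse), non-negative.
#' @param conversion `"standard"` (0.0555) or `"rounded"` (0.06).
#' @return Converted values; the two functions are exact inverses.
#' @export
#' @examples
#' glucose_mgdl_to_mmol(100)                         # 5.55
#' glucose_mgdl_to_mmol(100, conversion = "rounded") # 6
glucose_mgdl_to_mmol <- function(x, conversion = c("standard", "rounded")) {
  conversion <- match.arg(conversion)
  if (any(!is.finite(x)) || any(x < 0)) abort("Glucose must be finite and non-negative.")
  x * .glucose_factors[[conversion]]
}

#' @rdname glucose_mgdl_to_mmol
#' @export
glucose_mmol_to_mgdl <- function(x, conversion = c("standard", "rounded")) {
  conversion <- match.arg(conversion)
  if (any(!is.finite(x)) || any(x < 0)) abort("Glucose must be finite and non-negative.")
  x / .glucose_factors[[conversion]]
}

#' Add HOMA-IR to a cohort table
#'
#' Uses `insulin_uiu_ml` with `glucose_mmol` if present, otherwise converts
#' `glucose_mgdl` via [glucose_mgdl_to_mmol()]. Rows with missing or
#' non-positive inputs get `NA`.
#'
#' @param data Cohort data frame.
#' @param conversion Passed to [glucose_mgdl_to_mmol()] when converting.
#' @return `data` as a tibble plus a `homa_ir` column.
#' @export
add_homa_ir <- function(data, conversion = c("standard", "rounded")) {
  stopifnot(is.data.frame(data))
  conversion <- match.arg(conversion)
  out <- tibble::as_tibble(data)
  if (!"insulin_uiu_ml" %in% names(out)) {
    abort("Missing column `insulin_uiu_ml` for the HOMA-IR stage.")
  }
  glu_mmol <- if ("glucose_mmol" %in% names(out)) {
    out$glucose_mmol
  } else if ("glucose_mgdl" %in% names(out)) {
    ifelse(is.finite(out$glucose_mgdl) & out$glucose_mgdl >= 0,
           out$glucose_mgdl * .glucose_factors[[conversion]], NA_real_)
  } else {
    abort("Need a `glucose_mmol` or `glucose_mgdl` column for the HOMA-IR stage.")
  }
  ok <- is.finite(out$insulin_uiu_ml) & out$insulin_uiu_ml > 0 &
    is.finite(glu_mmol) & glu_mmol > 0
  out$homa_ir <- NA_real_
  out$homa_ir[ok] <- out$insulin_uiu_ml[ok] * glu_mmol[ok] / 22.5
  out
}
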