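test_that("the constants file loads both sex-specific models", {
  cf <- frs_coefficients()
  expect_named(cf, c("female", "male"))
  expect_true(all(c("b_ln_age", "s0_10", "lp_mean") %in% names(cf$female)))
  expect_gt(cf$female[["b_ln_age"]], 0)
  expect_lt(cf$male[["b_ln_hdl"]], 0)
})

test_that("the risk function reproduces the 2008 reference's worked example", {
  # D'Agostino et al. (2008): 61-year-old woman, TC 180, HDL 47, untreated
  # SBP 124, smoker, non-diabetic -> 10-year general CVD risk 10.48%.
  risk <- general_cvd_risk(61, "F", 124, FALSE, TRUE, FALSE, 180, 47)
  expect_equal(risk, 0.1048, tolerance = 0.002)
})

test_that("risk moves in the documented direction for each factor", {
  base <- list(age = 50, sex = "M", sbp = 125, trt = FALSE, smk = FALSE,
               dm = FALSE, tc = 180, hdl = 45)
  r <- function(l) general_cvd_risk(l$age, l$sex, l$sbp, l$trt, l$smk, l$dm, l$tc, l$hdl)
  r0 <- r(base)
  expect_gt(r(modifyList(base, list(age = 60))), r0)
  expect_gt(r(modifyList(base, list(sbp = 145))), r0)
  expect_gt(r(modifyList(base, list(smk = TRUE))), r0)
  expect_gt(r(modifyList(base, list(dm = TRUE))), r0)
  expect_gt(r(modifyList(base, list(tc = 240))), r0)
  expect_lt(r(modifyList(base, list(hdl = 70))), r0)
  expect_gt(r(modifyList(base, list(trt = TRUE))), r0)  # treated SBP beta larger
  for (sex in c("F", "M")) {
    expect_gt(general_cvd_risk(60, sex, 125, FALSE, FALSE, FALSE, 180, 45),
              general_cvd_risk(50, sex, 125, FALSE, FALSE, FALSE, 180, 45))
  }
})

test_that("invalid risk inputs are rejected, extreme ages warn", {
  expect_error(general_cvd_risk(50, "F", -1, FALSE, FALSE, FALSE, 180, 45), "sbp")
  expect_error(general_cvd_risk(50, "F", 120, FALSE, FALSE, FALSE, -2, 45), "total_chol")
  expect_error(general_cvd_risk(50, "F", 120, FALSE, FALSE, FALSE, 180, 0), "hdl_chol")
  expect_error(general_cvd_risk(50, "X", 120, FALSE, FALSE, FALSE, 180, 45), "sex")
  expect_warning(general_cvd_risk(105, "F", 120, FALSE, FALSE, FALSE, 180, 45),
                 "outside 20-100")
})

test_that("vascular age has the reference profile as a fixed point", {
  ref <- frs_reference()
  for (sex in c("F", "M")) {
    for (a in c(30, 47, 61, 74)) {
      va <- vascular_age(a, sex, ref$sbp, FALSE, FALSE, FALSE,
                         ref$total_chol, ref$hdl_chol)
      expect_equal(va$vascular_age, a, tolerance = 1e-6)
      expect_identical(va$flag, "ok")
    }
  }
})

test_that("worse-than-reference factors raise vascular age above chronological", {
  va <- vascular_age(50, "F", 160, FALSE, FALSE, FALSE, 180, 45)
  expect_gt(va$vascular_age, 50)
  vb <- vascular_age(50, "M", 125, FALSE, TRUE, FALSE, 180, 45)
  expect_gt(vb$vascular_age, 50)
})

test_that("bisection agrees with the 0.001-year grid oracle on a fixed profile", {
  p <- fixture_risk_profile()
  va <- vascular_age(p$age, p$sex, p$sbp, p$on_htn_treatment, p$smoker,
                     p$diabetic, p$total_chol, p$hdl_chol)
  target <- general_cvd_risk(p$age, p$sex, p$sbp, p$on_htn_treatment,
                             p$smoker, p$diabetic, p$total_chol, p$hdl_chol)
  expect_equal(va$vascular_age, oracle_vascular_age_grid(target, p$sex),
               tolerance = 0.002)
})

test_that("inversion is consistent: reference risk at VA equals the subject's risk", {
  set.seed(21)
  ref <- frs_reference()
  for (i in 1:25) {
    p <- random_risk_profile()
    target <- general_cvd_risk(p$age, p$sex, p$sbp, p$on_htn_treatment,
                               p$smoker, p$diabetic, p$total_chol, p$hdl_chol)
    va <- vascular_age(p$age, p$sex, p$sbp, p$on_htn_treatment, p$smoker,
                       p$diabetic, p$total_chol, p$hdl_chol)
    if (va$flag == "ok") {
      back <- suppressWarnings(general_cvd_risk(
        va$vascular_age, p$sex, ref$sbp, FALSE, FALSE, FALSE,
        ref$total_chol, ref$hdl_chol
      ))
      expect_equal(back, target, tolerance = 1e-9)
    }
  }
})

test_that("out-of-bracket targets are clipped and flagged", {
  hi <- vascular_age(74, "M", 175, TRUE, TRUE, TRUE, 300, 25)
  expect_identical(hi$flag, "saturated")
  expect_equal(hi$vascular_age, 120)
  lo <- suppressWarnings(vascular_age(21, "M", 95, FALSE, FALSE, FALSE, 120, 95))
  expect_identical(lo$flag, "floored")
  expect_equal(lo$vascular_age, 15)
})

test_that("vascular ageing is the signed difference", {
  expect_equal(vascular_ageing(51.5, 43.4), 8.1)
  expect_equal(vascular_ageing(40, 40), 0)
  expect_equal(vascular_ageing(30, 40), -10)
  expect_error(vascular_ageing(NaN, 40), "finite")
})

test_that("add_framingham fills columns and tolerates incomplete rows", {
  d <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    age_years = c(50, 61, NA), sex = c("M", "F", "F"),
    sbp_mmhg = c(130, 124, 120), htn_treated = c(0, 0, 0),
    smoker = c(0, 1, 0), diabetes = c(0, 0, 0),
    tc_mgdl = c(200, 180, 190), hdl_mgdl = c(45, 47, 50)
  )
  out <- add_framingham(d, quiet = TRUE)
  expect_equal(out$frs_risk[2], 0.1048, tolerance = 0.002)
  expect_equal(out$vascular_ageing, out$vascular_age - out$age_years)
  expect_true(is.na(out$frs_risk[3]))
  expect_error(add_framingham(d[, -2]), "age_years")
})
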