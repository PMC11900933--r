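---
title: "Comparing epigenetic, chronological and vascular age in two-group cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing epigenetic, chronological and vascular age in two-group cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epivasc)
library(dplyr)
```

## The analytic chain

epivasc implements the analysis layer of a case-control comparison of three
age measures in adults: chronological age, epigenetic age from a five-CpG
blood methylation clock, and vascular ("heart") age from the 2008 Framingham
general cardiovascular risk function. The motivating design contrasts a rare
syndromic obesity group (Prader-Willi syndrome, PWS) against controls with
essential obesity (EOB), asking whether the case group is epigenetically
older or younger than its calendar age, and whether any difference is
mirrored by vascular ageing. The package takes per-subject tables
(samples x variables), so every stage is a data-frame-in, tibble-out
function that composes with the pipe.

## The five-CpG clock

Epigenetic age is a fixed linear function of percent methylation (pyrosequencing
scale, 0-100) at one CpG site in each of ELOVL2, C1orf132/MIR29B2C, TRIM59,
KLF14 and FHL2:

$$\hat{a} = \beta_0 + \sum_{i=1}^{5} \beta_i \, m_i$$

with the published coefficients held by `clock_model()`:

```{r}
tidy(clock_model())
```

The coefficients are used as printed, to full double precision; the package
never re-estimates them. C1orf132 is the only site whose methylation falls
with age, hence the sole negative coefficient. Two modelling consequences
are deliberate:

* **No clamping.** The linear model is unbounded; extreme profiles can yield
  predicted ages below zero. The raw value is returned with a warning,
  because the model defines no floor and truncation would bias downstream
  group statistics.
* **Percent, not fraction.** Inputs are percentages. A profile whose five
  values all lie in (0, 1] almost certainly carries fractions; the reader
  warns by default and rejects under `strict_percent = TRUE`. The check is
  per profile, not per value, because single sites (KLF14 in the young) are
  legitimately below 1%.

Age acceleration is the signed difference `epigenetic - chronological`;
negative values mean an epigenetically younger profile.

## Framingham risk and vascular age

`general_cvd_risk()` evaluates the sex-specific lipid-based 2008 Framingham
general-CVD Cox model,

$$\text{risk}_{10} = 1 - S_0(10)^{\exp(\ell - \bar{\ell})},$$

where the linear predictor $\ell$ is built on log age, log total cholesterol,
log HDL, log SBP (with a separate coefficient under antihypertensive
treatment) plus smoking and diabetes indicators. The constants are
transcribed from D'Agostino et al. (Circulation, 2008) into
`inst/extdata/frs_general_cvd_2008.csv` — a version-pinned, commented file
rather than magic numbers in code — and the loader refuses files with
missing terms. The test suite pins the transcription to that reference's
worked example (61-year-old woman, TC 180, HDL 47, untreated SBP 124,
smoker, non-diabetic: 10-year risk 10.48%).

Vascular age inverts this function: the age at which a same-sex person with
all modifiable factors at normal levels (`frs_reference()`: untreated SBP
125 mmHg, TC 180 mg/dL, HDL 45 mg/dL, non-smoker, non-diabetic) attains the
subject's predicted risk. Because the reference risk is strictly increasing
in age, the inversion is a one-dimensional root-finding problem, solved by
bisection over 15-120 years to a risk tolerance of 1e-10. Numerical
contracts, all tested:

* the reference profile is a fixed point (`vascular_age` recovers
  chronological age to within 1e-6 years across 30-74 for both sexes);
* agreement with an independent 0.001-year grid search to within 0.002 years;
* targets outside the bracket are clipped to 15 or 120 years and flagged
  `"floored"`/`"saturated"` instead of extrapolated.

The risk function was derived for ages 30-74; outside 20-100 the package
computes anyway but warns, since case cohorts of interest include adults in
their late twenties. The lipid-based (not BMI-based) variant is implemented,
matching the listed inputs; the BMI variant would be a separate constants
file. `vascular_ageing()` is `vascular age - chronological age`.

## HOMA-IR and units

`homa_ir()` is `insulin [uIU/mL] x glucose [mmol/L] / 22.5`. Glucose
conversion from mg/dL uses 0.0555 mmol/L per mg/dL by default — the factor
HOMA calculators conventionally use — with the coarser 0.06 sometimes seen
in assay documentation available via `conversion = "rounded"` for
bit-compatibility with analyses that used it.

## Group statistics

The reporting layer mirrors clinical "Table 1" conventions:

* **Continuous variables**: median [25th; 75th percentile] by group with
  type-7 (linear interpolation) quantiles — R's default, stated here because
  quantile conventions differ — compared with the two-sided unpaired
  Mann-Whitney rank-sum test. The exact null distribution is used when the
  pooled sample is at most 20 without ties; otherwise the normal
  approximation with tie-variance and continuity corrections. A paired
  signed-rank test exists separately (`signed_rank_test()`) for genuinely
  paired designs; it is *not* used for two independent groups of unequal
  size, where only the unpaired test is meaningful.
* **Categorical variables**: Pearson chi-squared without Yates correction by
  default (a flag enables it), warning when any expected count is below 5.
* **Correlations**: Spearman's rho as the Pearson correlation of mid-ranks.
  The two-sided p-value is an exact full-permutation enumeration for n <= 8
  and the t approximation on n - 2 degrees of freedom above that; the
  enumeration bound is where n! stays below ~40k evaluations. Constant
  inputs leave rho undefined and flagged rather than erroring.
* **Display**: p-values render as `ns` (>= 0.05), `=0.0xx`, or `<0.001`;
  the raw p is always kept alongside. No multiple-testing correction is
  applied by default, matching the single-comparison convention of the
  motivating design; `p.adjust` can be applied to any result column.

## The synthetic cohort generator

No subject-level data are distributed with the package, so
`generate_cohort()` creates cohorts with the statistical structure the
analysis assumes, for testing and power/recovery studies. Defaults encode
the motivating study's structure: 36 controls vs 24 cases; clinical
variables (BMI, SBP, glucose, insulin, TC, HDL, TG, hsCRP) drawn from
log-normal marginals parameterised by the published group medians and
quartiles (log-normal because these variables are positive and
right-skewed, and median/IQR is all the anchor tables report); binary
covariates from the published prevalences.

The methylation-age link is constructed, not fitted: each site moves
linearly with an effective age `age + offset` (offset -12 years in the case
group by default, matching the direction and rough size of the published
group difference in epigenetic age), with slope signs matching the clock
coefficients. Two calibration identities make the construction exact at
zero noise: slopes are rescaled so `sum(coef * slope) = 1`, and the
C1orf132 baseline is solved so `sum(coef * baseline) = -intercept`. The
clock then returns `age + offset` exactly, and every case subject is
epigenetically younger than its calendar age — the qualitative signature
the analysis is designed to detect. Gaussian per-site noise (sd 6% for four
sites, 2% for low-methylation KLF14) gives a clock residual of about 4.5
years, chosen so within-group epigenetic-chronological correlations land in
the strong-but-imperfect range (rho ~0.9) typical of pyrosequencing clocks.
Methylation is clamped to [0, 100] after noise; configurations where more
than 20% of values clamp warn that the structure is degraded. Ages are
rejection-sampled into 18-80 years (an adult in-patient cohort).

What the generator does **not** emulate: between-variable correlation
structure beyond the methylation-age link (BMI and SBP are drawn
independently, unlike real metabolic covariates), genotype subclasses,
growth-hormone therapy effects, or measurement rounding. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers known
structure from data of the assumed form — not that real cohorts have that
form.

`recover_offset()` closes the loop: on a generated cohort it returns the
difference in group median age acceleration, which estimates the configured
offset. The acceptance suite checks recovery of a -12-year offset to within
+/- 1.5 years at 500 subjects per group, and a null offset to within 1 year.

## Problem sizes and reproducibility

The test suite runs enumeration oracles up to pooled n = 12 (C(12,6) = 924
assignments) for the rank-sum test and n = 8 (40,320 permutations) for
Spearman; the type-I error study uses 10,000 null simulations at 12 vs 12;
the inversion oracle scans a 0.001-year grid over 15-120 years for 100
random profiles; calibration checks span 200 seeded generator runs. These
sizes make the whole suite run in about two minutes while keeping every
Monte-Carlo band comfortably narrower than the tested tolerance. All
simulations are seeded; `generate_cohort()` is byte-reproducible given
(config, seed), and `run_pipeline()` is a pure function of its inputs.

## A worked run

```{r, message = FALSE, warning = FALSE}
cohort <- generate_cohort(cohort_sim_config(), seed = 1)
report <- run_pipeline(cohort)
report$table1
```

```{r}
report$age_correlations %>%
  select(group, x, y, rho, n, p_display)
```

```{r, fig.width = 6, fig.height = 3.5}
autoplot(report, type = "correlation")
```

## Known limitations

* The clock is a fixed published model; no uncertainty is attached to its
  predictions, and it is only as transportable as the population it was
  trained in.
* Vascular age saturates at the bracket ends by design; cohorts with many
  extreme-risk subjects will pile up at the flags rather than spread out.
* The Framingham constants file implements the lipid-based variant only.
* The generator's independence assumptions above; its medians/IQRs are
  calibration anchors, not a generative model of the source population.
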