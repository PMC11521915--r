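---
title: "Methods: a blended payment framework for district hospitals"
author: "blendedpay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a blended payment framework for district hospitals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendedpay)
```

## The payment model

Public district hospitals in India are typically financed through
historical line-item budgets that ignore both the population's health
needs and the volume of care actually delivered. `blendedpay` implements
an alternative: a *blended* provider-payment design in which each of the
hospital's three service blocks is paid through the mechanism best
suited to it.

* **Outpatient care — risk-adjusted global budget.** The annual
  outpatient budget is a linear function of district demand- and
  supply-side indicators:

  $$B_{op} = \alpha + \delta_{tier} + \beta_{pop}\,x_{pop}
    + \beta_{beds}\,x_{beds} + \beta_{imr}\,x_{imr}
    + \beta_{age}\,x_{age} + \beta_{util}\,x_{util},$$

  where $x_{pop}$ is the district population in lakhs, $x_{beds}$ the
  hospital's bed strength, $x_{imr}$ the district infant mortality rate
  (a robust, regularly published proxy of population health need),
  $x_{age}$ the percentage of the population under 5 or over 60 years,
  and $x_{util}$ the percentage utilization of public health services.
  The city-tier offsets $\delta_{tier}$ (tier 1 is the reference)
  absorb price-level differences across city sizes.
  `canonical_outpatient_model()` packages the published coefficient set
  (intercept ₹75.4M; tier-2 −₹34.3M; tier-3 −₹51.4M; ₹89,121 per bed;
  ₹565,977 per IMR unit; R² 0.5603), and `fit_outpatient_model()`
  re-estimates it by OLS from any facility table.

* **Inpatient care — case-based bundled payment.** Expected annual
  admissions per specialty follow bed-capacity throughput,
  $n_s = \text{beds} \times \text{share}_s \times \text{BOR}_s \times
  365 / \text{ALOS}_s$. Admissions split into an insured share priced at
  the case-mix-weighted health-benefit-package (HBP) tariff and an
  uninsured remainder priced at the specialty's weighted cost per
  admission (packaged values ₹9,867–₹14,104 across the seven
  specialties). The budget is the sum over specialties, hence exactly
  linear in beds.

* **Indirect services — per-bed global budget.** Administration,
  registration, governance, biomedical waste, laundry and dietetics
  scale with hospital size; the budget is `beds × rate`, with the
  packaged secondary rate of ₹163,969 per bed per year and a tertiary
  (medical-college) rate of ₹294,441. `estimate_per_bed_rate()` computes
  the pooled ratio $\sum_i c_i / \sum_i b_i$ from observed facilities —
  pooled rather than a mean of per-hospital ratios, because a per-bed
  *average cost* weights hospitals by their size.

`allocate()` composes the three streams into a `hospital_payout` whose
`total` is their exact sum; `national_rollup()` aggregates payouts to
stream means, ranges, max/min ratios, stream shares, and per-state
variation.

## Assumptions and diagnostics

The outpatient model is an OLS fit, justified by the usual battery:
Kolmogorov–Smirnov normality tests of the regressand and residuals with
the Lilliefors correction (parameters are estimated, so the plain KS
null distribution would be anticonservative), the studentized
Breusch–Pagan test for homoscedasticity, and variance inflation
factors. Because the city tier enters as one categorical term with two
dummies, per-dummy VIFs have an intrinsic floor of about 3.7 under the
7/29/64 tier composition (the dummies are mutually correlated at
−0.85); the diagnostics therefore report the generalized VIF rescaled
as $GVIF^{1/Df}$, which is comparable to an ordinary VIF and to the
conventional <5 threshold.

## The synthetic-data generator

The facility cost data behind the framework (a 27-hospital costing
survey, a national bed registry, an insurance claims distribution) are
not redistributable, so `blendedpay` ships a generator that emulates
their statistical structure:

1. `generate_base_sample()` draws a small tier-stratified survey
   (default 5/9/13 = 27 hospitals, proportional to the analysis
   composition below) with covariates uniform over per-tier ranges, and
   generates outpatient cost as the truth model's linear predictor plus
   Gaussian noise.
2. `expand_mvnd()` performs the tier-wise multivariate-normal
   expansion: per tier it estimates the mean and covariance of the
   numeric facility fields, shrinks the covariance
   ($\Sigma' = (1-\lambda)\Sigma + \lambda\,\mathrm{diag}\,\Sigma$,
   default $\lambda = 0.1$) to remain positive semidefinite in small
   strata, and samples to the analysis composition of 7 tier-1, 29
   tier-2 and 64 tier-3 facilities (100 in all). All numeric fields
   enter the expansion jointly — covariates, cost components and
   staffing — so their correlations survive; categorical fields (state,
   specialty bed shares) are resampled from the tier's base records. A
   resampling-with-replacement alternative is available via
   `method = "bootstrap"`.
3. `generate_national_registry()` builds an 845-hospital registry with
   beds, district indicators, staffing and capital stock (costs are
   `NA`: a registry records capacity, not observed costs).

### Default conditions, and why

* **Tier composition 7/29/64** and **845 registry hospitals** are the
  study conditions themselves.
* **Covariate ranges** (beds 150–700 rising with tier, IMR 15–60
  falling with tier, district population 8–80 lakhs, dependent-age
  share 12–22%, public utilization 20–70%) are plausible Indian
  district-hospital ranges. They deliberately overlap across tiers so
  the tier dummies are not near-deterministic functions of the
  continuous covariates (keeping every VIF below 5), and they keep the
  truth model's linear predictor comfortably positive — real outpatient
  budgets are never near zero, and a floored cost would censor the
  Gaussian error structure the generator promises.
* **noise_sd = ₹22M** places the fitted R² near the published 0.5603
  under those ranges (the generator emulates the model's stated
  explanatory power, not just its coefficients).
* **Cost levels**: indirect cost is generated near ₹163,969 per bed and
  inpatient cost near ₹700k per bed, the levels the framework itself
  reports; capital stock near ₹1.5M per bed.
* **Shrinkage λ = 0.1** is the smallest round value that renders the
  7-record tier-1 covariance usable; λ = 0 with a singular covariance
  is an explicit error advising shrinkage rather than a silent fix.
* Sampled values outside physical bounds (negative costs, IMR < 0,
  percentages outside [0,100]) are clipped and counted; bed and
  staffing counts are rounded. The clip count is attached to the output
  and reported as a message.

### What the generator does *not* emulate

The expansion reproduces first and second moments per tier, not the
skewness, outliers or cluster structure of real facility costs; the
registry's states are a label set, not a calibrated geography; and the
HBP tariff table shipped as `hbp_tariffs_synthetic.csv` is a synthetic
stand-in (the operational tariff list is programme data — supply it via
`read_tariff_table()` for real allocations). Passing tests therefore
demonstrate the *machinery* — estimator calibration, conservation,
scenario arithmetic — under the stated statistical structure, not
agreement with any particular real hospital's budget.

## Upgrade scenarios

* **Staffing-standards upgrade (`apply_iphs()`).** The outpatient
  stream absorbs the staffing-shortfall cost
  ($\sum_c \max(0, \text{required}_c - \text{current}_c) \times
  \text{salary}_c$, surpluses never offset) and the annualized capital
  catch-up (a flat 20% of the existing capital stock per year —
  upgrades are gradual, so the full gap is not budgeted at once). The
  inpatient stream is recomputed at `beds × iphs_bed_uplift`: the
  upgrade's extra drugs and consumables are volume-driven, so they ride
  on the case-based stream automatically. The indirect stream is
  unchanged (per-bed indirect needs are standard-independent). The
  default uplift is 1.0 (no volume growth); published national
  estimates for the upgrade imply a volume factor near 2.3, which the
  acceptance script uses as its scenario condition. Both the
  outpatient/inpatient attribution of the shortfall and the stream
  receiving the capital term are configurable; defaults send both to
  the outpatient stream, consistent with the inpatient stream being
  purely volume-priced.
* **Medical-college conversion (`apply_medical_college()`).**
  Outpatient care switches to a tertiary risk-adjustment model,
  inpatient care to tertiary tariffs (or a multiplier on the secondary
  budget), indirect services to the ₹294,441 per-bed rate. The tertiary
  regression and tariff set are not public; when absent, the package
  substitutes clearly flagged synthetic placeholders — the secondary
  coefficient set (published stream means imply the tertiary outpatient
  level is close to the secondary one) and an inpatient multiplier of
  2.23 (the published +123% inpatient uplift). Every payout built on
  placeholders carries `tertiary_placeholder` /
  `tertiary_tariff_placeholder` provenance flags, and placeholders can
  be disabled (`allow_placeholders = FALSE`) to force real inputs.

## Numerical choices

* Admissions stay fractional through the costing; rounding only ever
  happens in display, which keeps the budget additive and
  order-independent.
* Negative outpatient predictions (possible for small tier-3 hospitals
  with high dependent-age shares) are floored at a configurable minimum
  (default 0) with a warning, never silently.
* Ratios are reported raw and rounded to one decimal only in print
  methods; stream shares always sum to 100 exactly because they are
  computed from the same totals they describe.
* Comparison with actual expenditure excludes zero-actual hospitals
  from percentage deviations (flagged and counted instead of dividing
  by zero).
* City-tier classification from population uses configurable
  thresholds (tier 1 above 50 lakhs, tier 2 from 10 lakhs), since only
  the ordering, not the cutoffs, is standardized.
* All randomness is scoped: every generator takes an explicit seed and
  restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the calibration studies
at 200 replicate fits (confidence-interval coverage), 500 replicate
fits (Breusch–Pagan size, in the test suite), a 10,000-sample
law-of-large-numbers check of the expansion, 1,000 random weight
vectors for the cost-bracketing property, and a full 845-hospital
national allocation per scenario. These sizes put Monte-Carlo error
well inside the asserted bands while the whole suite stays in the
tens of seconds.

## Limitations

The generator's covariance structure is estimated from its own small
base strata, so the expanded sample is *not* exactly the homoscedastic
linear-Gaussian design the base generator produces: pooled OLS on the
expanded sample absorbs small per-tier misspecifications. Calibration
checks (coverage, Breusch–Pagan size) therefore run on directly
generated samples, and fits on expanded samples should be read as the
intended analysis procedure, not as a calibration experiment. The
inpatient model prices expected capacity-driven volume, not realized
claims; no DRG grouping, adjudication or disease-wise breakdown of
uninsured admissions is attempted. Uncertainty in the fitted
coefficients is reported (SEs, CIs) but not propagated into payouts.
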