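# blendedpay

Simulation and allocation tools for a **blended provider-payment
framework** for public-sector district hospitals. Instead of historical
line-item budgets, each hospital's annual payout is built from three
streams, each paid through the mechanism suited to it:

| stream | mechanism | driver |
|---|---|---|
| outpatient care | risk-adjusted global budget | district need & supply indicators |
| inpatient care | case-based bundled payment | expected admissions × package tariffs |
| indirect services | per-bed global budget | bed strength |

The outpatient budget is a linear model of district indicators,

> B_op = α + δ_tier + β_pop·pop + β_beds·beds + β_imr·IMR + β_age·age% + β_util·util%,

with city-tier offsets (tier 1 reference), district population in
lakhs, bed strength, infant mortality rate as the population-health
proxy, the share of the population under 5 / over 60, and
public-sector utilization. The package ships the published coefficient
set (intercept ₹75.4M, ₹89,121 per bed, ₹565,977 per IMR unit, …,
R² = 0.5603) and can refit it by OLS — with a Lilliefors/KS,
Breusch–Pagan and VIF diagnostic battery — from any facility table.
Inpatient admissions follow bed throughput
(beds × share × BOR × 365 / ALOS) and are priced through a
health-benefit-package tariff case-mix plus specialty-level weighted
costs for uninsured cases; indirect services are paid at ₹163,969 per
bed per year (₹294,441 for medical colleges).

Because the underlying facility costing data are not redistributable,
the package includes a tier-stratified synthetic generator (a small
base survey expanded per tier with a multivariate normal model to the
7/29/64 analysis composition, plus an 845-hospital national registry),
upgrade scenarios (public-health staffing standards; medical-college
conversion), national budget-impact rollups, and comparison against
actual expenditure. It is aimed at health-financing researchers and
analysts who want to stress-test provider-payment designs before any
real allocation data are on the table.

## Worked example

Price one 400-bed tier-2 district hospital under existing standards and
under the staffing-standards upgrade:

```r
library(blendedpay)

h <- data.frame(
  hospital_id = "DH-Salem", state = "Tamil Nadu", district_id = "D-Salem",
  city_tier = 2L, population_lakhs = 35, imr = 28, pct_young_old = 18,
  pct_public_utilization = 45, beds = 400,
  op_cost = NA, ip_cost = NA, indirect_cost = NA, capital_cost = 6e8,
  staff_doctor = 70, staff_paramedical = 190, staff_support = 105,
  share_paediatrics = 0.14, share_general_medicine = 0.26,
  share_obstetrics_gynaecology = 0.20, share_ent = 0.07,
  share_general_surgery = 0.16, share_ophthalmology = 0.06,
  share_orthopedics = 0.11)

allocate(h)[c("outpatient", "inpatient", "indirect", "total")]
#>   outpatient inpatient indirect     total
#> 1   63700131 329554819 65587600 458842550

up <- allocate(h, scenario = "iphs",
               config = scenario_config(iphs_bed_uplift = 2.3))
up[c("outpatient", "inpatient", "indirect", "total")]
#>   outpatient inpatient indirect      total
#> 1  246400131 757976084 65587600 1069963815

percent_change(allocate(h)$total, up$total)
#> [1] 133.1964
```

Under existing standards the hospital receives ₹459M a year — ₹63.7M
outpatient (the tier-2 linear predictor), ₹330M inpatient (≈27,000
expected admissions priced through tariffs and weighted costs), ₹65.6M
indirect (400 × ₹163,969). The upgrade adds the staffing-shortfall
salaries and a 20% annualization of the ₹600M capital stock to the
outpatient stream and scales inpatient volume by 2.3, a 133% increase
in the total.

The published coefficient set prints in the familiar regression-table
layout:

```r
canonical_outpatient_model()
#> Outpatient risk-adjustment model (published)
#>   Intercept                            75,400,000  (SE 32,900,000; ...)
#>   Type of city: tier 2                -34,300,000  (SE 10,700,000; ...)
#>   ...
#>   R-squared 0.5603, adjusted R-squared 0.5268
```

A full synthetic national run is three lines:

```r
reg  <- generate_national_registry(845, seed = 1)
pay  <- allocate_payouts(reg)
national_rollup(pay)
```

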