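# Upgrade scenarios: (a) compliance with national public-health staffing
# standards for secondary hospitals ("IPHS"), adding the staffing
# shortfall cost and an annualized capital catch-up, with inpatient
# volume growth expressed as a bed-uplift factor; (b) conversion to a
# medical college (tertiary care), swapping in a tertiary outpatient
# model, tertiary tariffs and the tertiary per-bed indirect rate.

#' Staffing norms as a step function of bed size
#'
#' Required headcounts per cadre (doctor, paramedical, support) at a
#' given bed size: the row with the smallest `beds_max >= beds` applies.
#' Requirements must be non-decreasing in beds.
#'
#' @param norms data.frame with columns `beds_max` (last row may be
#'   `Inf`), `doctor`, `paramedical`, `support`.
#' @return Validated data.frame of class `staffing_norms`.
#' @export
staffing_norms <- function(norms) {
  need <- c("beds_max", staff_cadres())
  missing_cols <- setdiff(need, names(norms))
  if (length(missing_cols))
    stopf("norms missing columns: %s", paste(missing_cols, collapse = ", "))
  norms <- norms[order(norms$beds_max), , drop = FALSE]
  for (cadre in staff_cadres()) {
    v <- norms[[cadre]]
    if (any(v < 0)) stopf("%s requirement must be non-negative", cadre)
    if (is.unsorted(v)) stopf("%s requirement must be non-decreasing in beds",
                              cadre)
  }
  structure(as.data.frame(norms), class = c("staffing_norms", "data.frame"))
}

#' Default staffing norms and salary schedule
#'
#' Packaged step-function staffing requirements by bed size and annual
#' salary levels per cadre (INR/year), both stand-ins for the official
#' normative tables, which users should supply for real allocations (see
#' [read_staffing_norms()]).
#'
#' @return `default_staffing_norms()`: a [staffing_norms()] table;
#'   `default_salary_schedule()`: a named numeric vector of INR/year.
#' @export
default_staffing_norms <- function() {
  staffing_norms(data.frame(
    beds_max    = c(100, 200, 300, 400, 500, Inf),
    doctor      = c(25, 45, 65, 85, 105, 125),
    paramedical = c(80, 140, 200, 260, 320, 380),
    support     = c(40, 70, 100, 130, 160, 190)))
}

#' @rdname default_staffing_norms
#' @export
default_salary_schedule <- function() {
  c(doctor = 1440000, paramedical = 480000, support = 300000)
}

#' Read staffing norms or a salary schedule from CSV
#'
#' Norms CSV: columns `beds_max`, `doctor`, `paramedical`, `support`.
#' Salary CSV: columns `cadre`, `annual_salary`.
#'
#' @param path CSV path.
#' @return A [staffing_norms()] table / named salary vector.
#' @export
read_staffing_norms <- function(path) {
  staffing_norms(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_staffing_norms
#' @export
read_salary_schedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cadre", "annual_salary") %in% names(d)))
    stopf("salary schedule needs columns cadre, annual_salary")
  if (any(d$annual_salary <= 0)) stopf("salaries must be positive")
  stats::setNames(d$annual_salary, d$cadre)
}

#' Required staffing at a given bed size
#'
#' @param norms a [staffing_norms()] table.
#' @param beds bed count.
#' @return Named numeric vector of required headcounts per cadre.
#' @export
required_staffing <- function(norms, beds) {
  stopifnot(inherits(norms, "staffing_norms"))
  row <- which(norms$beds_max >= beds)[1]
  if (is.na(row)) row <- nrow(norms)
  stats::setNames(as.numeric(norms[row, staff_cadres()]), staff_cadres())
}

#' Annual cost of the staffing shortfall against the norms
#'
#' Per cadre, `max(0, required - current) * annual salary`; surpluses in
#' one cadre never offset shortfalls in another, so the cost is never
#' negative.
#'
#' @param current named numeric vector of current headcounts per cadre.
#' @param norms a [staffing_norms()] table.
#' @param beds bed count at which requirements are read off.
#' @param salaries named numeric vector of annual salaries (INR/year).
#' @return INR/year.
#' @export
staffing_shortfall_cost <- function(current, norms, beds, salaries) {
  req <- required_staffing(norms, beds)
  missing_sal <- setdiff(names(req)[req > 0], names(salaries))
  if (length(missing_sal))
    stopf("no salary for cadre: %s", paste(missing_sal, collapse = ", "))
  cur <- stats::setNames(rep(0, length(req)), names(req))
  cur[intersect(names(current), names(cur))] <-
    current[intersect(names(current), names(cur))]
  gap <- pmax(0, req - cur)
  sum(gap * salaries[names(req)])
}

#' Annualized capital catch-up
#'
#' Capital upgradation is budgeted gradually, at a fixed annual fraction
#' (default one-fifth) of the existing total capital stock.
#'
#' @param existing_capital capital stock (INR, >= 0).
#' @param fraction annual fraction in (0, 1] (default 0.20).
#' @return INR/year.
#' @export
capital_annualization <- function(existing_capital, fraction = 0.20) {
  if (any(existing_capital < 0)) stopf("existing_capital must be non-negative")
  check_number(fraction, "fraction", lower = 1e-12, upper = 1)
  existing_capital * fraction
}

#' Synthetic placeholder tertiary outpatient model
#'
#' The tertiary (medical-college) outpatient risk-adjustment coefficients
#' come from a costing of tertiary facilities that is not distributed
#' with this package. This placeholder reuses the secondary coefficient
#' set — consistent with published stream-level means, in which the
#' outpatient payment changes little relative to the inpatient and
#' indirect streams under a tertiary upgrade — and is flagged as
#' `synthetic_placeholder` in every payout that uses it.
#'
#' @return A [risk_model()] with provenance "synthetic_placeholder".
#' @export
synthetic_tertiary_model <- function() {
  m <- canonical_outpatient_model()
  m$provenance <- "synthetic_placeholder"
  m
}

# placeholder tertiary/secondary inpatient cost ratio used when no
# tertiary tariff set is supplied (tertiary bundled prices run a little
# over twice the secondary level)
tertiary_multiplier_placeholder <- 2.23

#' Scenario configuration
#'
#' Bundles everything the scenario operations need: the secondary payment
#' inputs (specialty profiles, tariff table, uninsured cost table,
#' per-bed indirect rates), the staffing-upgrade parameters, and the
#' tertiary inputs for the medical-college scenario.
#'
#' @param capital_annual_fraction annual fraction of existing capital
#'   budgeted for upgradation, in (0, 1] (default 0.20).
#' @param iphs_bed_uplift multiplicative factor (>= 1) on beds in the
#'   staffing-standards scenario, carrying the volume-driven growth of
#'   inpatient care (default 1.0, i.e. no volume growth).
#' @param op_shortfall_share fraction of the staffing-shortfall cost
#'   attributed to the outpatient stream (default 1; the remainder goes
#'   to the inpatient stream).
#' @param capital_stream stream receiving the capital annualization
#'   ("outpatient", default, or "inpatient").
#' @param tertiary_model optional [risk_model()] for tertiary outpatient
#'   care; when `NULL` and `allow_placeholders`, the synthetic
#'   placeholder is used and flagged.
#' @param tertiary_tariffs optional [tariff_table()] of tertiary HBP
#'   prices.
#' @param tertiary_tariff_multiplier optional scalar applied to the
#'   secondary inpatient budget instead of tertiary tariffs; when both
#'   tariff inputs are `NULL` and `allow_placeholders`, a placeholder
#'   multiplier of 2.23 is used and flagged.
#' @param allow_placeholders whether missing tertiary inputs may fall
#'   back to flagged synthetic placeholders (default TRUE).
#' @param rates an [indirect_rate_config()].
#' @param profiles a [specialty_profiles()] set.
#' @param tariffs a [tariff_table()] (secondary).
#' @param nonpmjay_costs named specialty cost vector.
#' @param outpatient_floor floor on predicted outpatient budgets.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(capital_annual_fraction = 0.20,
                            iphs_bed_uplift = 1.0,
                            op_shortfall_share = 1.0,
                            capital_stream = c("outpatient", "inpatient"),
                            tertiary_model = NULL,
                            tertiary_tariffs = NULL,
                            tertiary_tariff_multiplier = NULL,
                            allow_placeholders = TRUE,
                            rates = indirect_rate_config(),
                            profiles = default_specialty_profiles(),
                            tariffs = default_tariff_table(),
                            nonpmjay_costs = specialty_cost_table(),
                            outpatient_floor = 0) {
  capital_stream <- match.arg(capital_stream)
  check_number(capital_annual_fraction, "capital_annual_fraction", 1e-12, 1)
  check_number(iphs_bed_uplift, "iphs_bed_uplift", lower = 1)
  check_number(op_shortfall_share, "op_shortfall_share", 0, 1)
  structure(
    list(capital_annual_fraction = capital_annual_fraction,
         iphs_bed_uplift = iphs_bed_uplift,
         op_shortfall_share = op_shortfall_share,
         capital_stream = capital_stream,
         tertiary_model = tertiary_model,
         tertiary_tariffs = tertiary_tariffs,
         tertiary_tariff_multiplier = tertiary_tariff_multiplier,
         allow_placeholders = allow_placeholders,
         rates = rates, profiles = profiles, tariffs = tariffs,
         nonpmjay_costs = nonpmjay_costs,
         outpatient_floor = outpatient_floor),
    class = "scenario_config")
}

#' Adjust a hospital's payout for the staffing-standards upgrade
#'
#' Starting from the base payout: the outpatient stream absorbs the
#' staffing-shortfall cost (per `op_shortfall_share`) and, by default,
#' the annualized capital catch-up; the inpatient stream is recomputed at
#' `beds * iphs_bed_uplift`, carrying the volume-driven growth in drugs
#' and consumables; the indirect stream is unchanged (indirect needs per
#' bed are standard-independent).
#'
#' @param hospital one row of a facility table.
#' @param base_payout the hospital's payout under existing standards (a
#'   [hospital_payout()] row).
#' @param norms a [staffing_norms()] table.
#' @param salaries named salary vector (INR/year).
#' @param config a [scenario_config()].
#' @return A [hospital_payout()] row with scenario "iphs".
#' @export
apply_iphs <- function(hospital, base_payout, norms = default_staffing_norms(),
                       salaries = default_salary_schedule(),
                       config = scenario_config()) {
  if (is.null(norms)) stopf("staffing norms are required for the upgrade")
  beds <- hospital$beds[1]
  current <- stats::setNames(as.numeric(hospital[1, staff_cols()]),
                             staff_cadres())
  shortfall <- staffing_shortfall_cost(current, norms, beds, salaries)
  capital <- capital_annualization(hospital$capital_cost[1],
                                   config$capital_annual_fraction)
  op <- base_payout$outpatient + config$op_shortfall_share * shortfall
  ip <- inpatient_budget(beds * config$iphs_bed_uplift,
                         profiles_for_hospital(hospital, config$profiles),
                         config$tariffs, config$nonpmjay_costs) +
    (1 - config$op_shortfall_share) * shortfall
  if (config$capital_stream == "outpatient") op <- op + capital
  else ip <- ip + capital
  hospital_payout(hospital$hospital_id[1], hospital$state[1], "iphs",
                  outpatient = op, inpatient = ip,
                  indirect = base_payout$indirect,
                  provenance = base_payout$provenance)
}

#' Payout for a hospital upgraded to a medical college
#'
#' Outpatient care is paid from the tertiary risk-adjustment model,
#' inpatient care from tertiary tariffs (or the secondary budget scaled
#' by `tertiary_tariff_multiplier`), and indirect services at the
#' tertiary per-bed rate. Missing tertiary inputs fall back to flagged
#' synthetic placeholders when `allow_placeholders` is set, and are an
#' error otherwise.
#'
#' @param hospital one row of a facility table.
#' @param config a [scenario_config()].
#' @return A [hospital_payout()] row with scenario "medical_college"; the
#'   `provenance` field lists any placeholders used.
#' @export
apply_medical_college <- function(hospital, config = scenario_config()) {
  flags <- character()
  model_t <- config$tertiary_model
  if (is.null(model_t)) {
    if (!config$allow_placeholders)
      stopf("tertiary outpatient model missing and placeholders disabled")
    model_t <- synthetic_tertiary_model()
  }
  if (identical(model_t$provenance, "synthetic_placeholder"))
    flags <- c(flags, "tertiary_placeholder")
  beds <- hospital$beds[1]
  op <- predict_outpatient_budget(
    model_t,
    hospital[1, c("city_tier", "population_lakhs", "imr", "pct_young_old",
                  "pct_public_utilization")],
    beds = beds, floor = config$outpatient_floor)
  profiles <- profiles_for_hospital(hospital, config$profiles)
  if (!is.null(config$tertiary_tariffs)) {
    ip <- inpatient_budget(beds, profiles, config$tertiary_tariffs,
                           config$nonpmjay_costs)
  } else {
    mult <- config$tertiary_tariff_multiplier
    if (is.null(mult)) {
      if (!config$allow_placeholders)
        stopf("tertiary tariffs missing and placeholders disabled")
      mult <- tertiary_multiplier_placeholder
      flags <- c(flags, "tertiary_tariff_placeholder")
    }
    ip <- mult * inpatient_budget(beds, profiles, config$tariffs,
                                  config$nonpmjay_costs)
  }
  ind <- indirect_budget(beds, config$rates$rate_medical_college)
  hospital_payout(hospital$hospital_id[1], hospital$state[1],
                  "medical_college", outpatient = op, inpatient = ip,
                  indirect = ind,
                  provenance = paste(flags, collapse = ";"))
}
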