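# Internal helpers: argument checking and facility-table validation.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Canonical district-hospital specialties
#'
#' The seven clinical specialties over which inpatient beds, admissions and
#' bundled-payment tariffs are organised.
#'
#' @return Character vector of the seven specialty names.
#' @export
dh_specialties <- function() {
  c("Paediatrics", "General Medicine", "Obstetrics and gynaecology",
    "Ear Nose and Throat", "General Surgery", "Ophthalmology", "Orthopedics")
}

# column-safe keys for the specialty share columns of a facility table
specialty_keys <- function() {
  c("paediatrics", "general_medicine", "obstetrics_gynaecology",
    "ent", "general_surgery", "ophthalmology", "orthopedics")
}

share_cols <- function() paste0("share_", specialty_keys())

staff_cadres <- function() c("doctor", "paramedical", "support")

staff_cols <- function() paste0("staff_", staff_cadres())

# required columns of a facility (hospital) table
facility_columns <- function() {
  c("hospital_id", "state", "district_id", "city_tier", "population_lakhs",
    "imr", "pct_young_old", "pct_public_utilization", "beds",
    "op_cost", "ip_cost", "indirect_cost", "capital_cost",
    staff_cols(), share_cols())
}

#' Validate a facility table
#'
#' Checks the structural invariants of a hospital table: required columns
#' present, tiers in \{1,2,3\}, positive populations, non-negative costs
#' and headcounts, percentages in [0,100], at least one bed per hospital,
#' and specialty bed shares summing to one.
#'
#' Cost columns may be `NA` (e.g. in a bed registry where facility costs
#' are not observed); when present they must be non-negative.
#'
#' @param hospitals data.frame with one row per hospital.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_facility_table <- function(hospitals) {
  if (!is.data.frame(hospitals) || nrow(hospitals) == 0L)
    stopf("facility table must be a data.frame with at least one row")
  missing_cols <- setdiff(facility_columns(), names(hospitals))
  if (length(missing_cols))
    stopf("facility table is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  if (!all(hospitals$city_tier %in% 1:3))
    stopf("city_tier must be 1, 2 or 3")
  if (any(hospitals$population_lakhs <= 0))
    stopf("population_lakhs must be positive")
  if (any(hospitals$imr < 0))
    stopf("imr must be non-negative")
  for (col in c("pct_young_old", "pct_public_utilization")) {
    if (any(hospitals[[col]] < 0 | hospitals[[col]] > 100))
      stopf("%s must lie in [0, 100]", col)
  }
  if (any(hospitals$beds < 1))
    stopf("beds must be >= 1")
  for (col in c("op_cost", "ip_cost", "indirect_cost", "capital_cost",
                staff_cols())) {
    v <- hospitals[[col]]
    if (any(!is.na(v) & v < 0)) stopf("%s must be non-negative", col)
  }
  shares <- as.matrix(hospitals[share_cols()])
  if (any(shares < 0)) stopf("specialty bed shares must be non-negative")
  bad <- abs(rowSums(shares) - 1) > 1e-9
  if (any(bad))
    stopf("specialty bed shares must sum to 1 (rows: %s)",
          paste(utils::head(which(bad), 5L), collapse = ", "))
  invisible(hospitals)
}

#' Classify a city tier from its population
#'
#' Tier is determined by total population with configurable thresholds:
#' above the first threshold is tier 1, between the two is tier 2,
#' otherwise tier 3.
#'
#' @param population_lakhs numeric vector, population in lakhs.
#' @param tier1_min,tier2_min thresholds in lakhs (defaults 50 and 10).
#' @return Integer vector of tiers in \{1,2,3\}.
#' @export
classify_city_tier <- function(population_lakhs, tier1_min = 50,
                               tier2_min = 10) {
  if (tier2_min >= tier1_min) stopf("tier2_min must be below tier1_min")
  ifelse(population_lakhs > tier1_min, 1L,
         ifelse(population_lakhs >= tier2_min, 2L, 3L))
}
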