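# Per-bed global budget for indirect services (administration, patient
# registration, governance, biomedical waste, laundry, dietetics).

#' Per-bed indirect service rates
#'
#' Default annual per-bed rates: 163,969 INR/bed for a secondary district
#' hospital and 294,441 INR/bed for a facility upgraded to a medical
#' college (tertiary indirect services).
#'
#' @param rate_base INR per bed per year, secondary standard.
#' @param rate_medical_college INR per bed per year, tertiary standard.
#' @return List of class `indirect_rate_config`.
#' @export
indirect_rate_config <- function(rate_base = 163969,
                                 rate_medical_college = 294441) {
  check_number(rate_base, "rate_base", lower = .Machine$double.eps)
  check_number(rate_medical_college, "rate_medical_college",
               lower = .Machine$double.eps)
  structure(list(rate_base = rate_base,
                 rate_medical_college = rate_medical_college),
            class = "indirect_rate_config")
}

#' Estimate the pooled per-bed indirect rate from observed facilities
#'
#' Pooled ratio: total indirect cost over total beds across the sample
#' (bed-weighted average cost per bed).
#'
#' @param hospitals facility table with observed `indirect_cost`.
#' @return INR per bed per year.
#' @export
estimate_per_bed_rate <- function(hospitals) {
  validate_facility_table(hospitals)
  if (any(is.na(hospitals$indirect_cost)))
    stopf("indirect_cost must be observed (non-NA) for all hospitals")
  total_beds <- sum(hospitals$beds)
  if (total_beds <= 0) stopf("total beds must be positive")
  sum(hospitals$indirect_cost) / total_beds
}

#' Annual per-bed global budget for indirect services
#'
#' @param beds bed count (>= 0).
#' @param rate INR per bed per year (> 0).
#' @return INR/year, `beds * rate`.
#' @export
indirect_budget <- function(beds, rate) {
  if (any(beds < 0)) stopf("beds must be non-negative")
  if (any(rate <= 0)) stopf("rate must be positive")
  beds * rate
}
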