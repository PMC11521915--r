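# Case-based bundled payment for inpatient care: expected specialty-level
# admissions from bed capacity (beds x share x occupancy x 365 / ALOS),
# split into insured (HBP-tariffed) and uninsured admissions, priced
# through the tariff case-mix and the specialty-level weighted costs.

#' Build a specialty profile set
#'
#' A specialty profile gives, for each of the seven inpatient
#' specialties, its share of hospital beds, average length of stay (ALOS,
#' days), bed occupancy rate (BOR, fraction) and the fraction of
#' admissions covered by the national insurance scheme's health benefit
#' packages (`pmjay_share`).
#'
#' @param profiles data.frame with columns `specialty`, `bed_share`,
#'   `alos`, `bor`, `pmjay_share`. Bed shares must sum to 1; `alos > 0`;
#'   `bor` and `pmjay_share` in [0, 1].
#' @return Validated data.frame of class `specialty_profiles`.
#' @export
specialty_profiles <- function(profiles) {
  need <- c("specialty", "bed_share", "alos", "bor", "pmjay_share")
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols))
    stopf("profiles missing columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(profiles$specialty))
    stopf("duplicated specialty in profiles")
  if (any(profiles$alos <= 0)) stopf("alos must be positive")
  for (col in c("bed_share", "bor", "pmjay_share"))
    if (any(profiles[[col]] < 0 | profiles[[col]] > 1))
      stopf("%s must lie in [0, 1]", col)
  if (abs(sum(profiles$bed_share) - 1) > 1e-9)
    stopf("bed shares must sum to 1 (got %.12f)", sum(profiles$bed_share))
  structure(as.data.frame(profiles),
            class = c("specialty_profiles", "data.frame"))
}

#' Default specialty profile set
#'
#' Packaged survey-style defaults for the seven specialties (bed shares,
#' ALOS, occupancy, insured share), config-overridable everywhere they
#' are consumed.
#'
#' @return A [specialty_profiles()] data.frame.
#' @export
default_specialty_profiles <- function() {
  specialty_profiles(data.frame(
    specialty = dh_specialties(),
    bed_share   = c(0.14, 0.26, 0.20, 0.07, 0.16, 0.06, 0.11),
    alos        = c(4.0, 5.0, 3.5, 2.5, 5.5, 2.0, 6.0),
    bor         = c(0.75, 0.85, 0.80, 0.55, 0.75, 0.60, 0.70),
    pmjay_share = c(0.35, 0.30, 0.45, 0.40, 0.45, 0.50, 0.45)))
}

#' Substitute a hospital's own specialty bed shares into a profile set
#'
#' @param hospital one row of a facility table (with `share_*` columns).
#' @param profiles a [specialty_profiles()] set supplying ALOS, BOR and
#'   insured shares.
#' @return A [specialty_profiles()] set with the hospital's bed shares.
#' @export
profiles_for_hospital <- function(hospital, profiles) {
  shares <- as.numeric(hospital[1, share_cols()])
  profiles <- as.data.frame(profiles)
  key <- stats::setNames(specialty_keys(), dh_specialties())
  idx <- match(paste0("share_", key[profiles$specialty]), share_cols())
  profiles$bed_share <- shares[idx] / sum(shares)
  specialty_profiles(profiles)
}

#' Expected annual admissions in a specialty
#'
#' Bed-capacity throughput: `beds * bed_share * bor * 365 / alos`,
#' kept real-valued (no rounding) so that costing is order-independent.
#'
#' @param beds hospital bed count (>= 0).
#' @param profiles a [specialty_profiles()] set (or any data.frame with
#'   `bed_share`, `bor`, `alos`).
#' @return Named numeric vector of admissions/year per specialty.
#' @export
expected_admissions <- function(beds, profiles) {
  if (any(beds < 0)) stopf("beds must be non-negative")
  if (any(profiles$alos <= 0)) stopf("alos must be positive")
  stats::setNames(beds * profiles$bed_share * profiles$bor * 365 /
                    profiles$alos,
                  profiles$specialty)
}

#' Specialty-level weighted cost tables (uninsured admissions)
#'
#' `specialty_cost_table()` returns the packaged per-admission weighted
#' costs for admissions outside the insurance benefit packages;
#' `read_specialty_cost_table()` reads a user table from CSV (columns
#' `specialty`, `cost_per_admission`).
#'
#' @param path CSV path (for the reader).
#' @return Named numeric vector: INR per admission, by specialty.
#' @export
specialty_cost_table <- function() {
  read_specialty_cost_table(
    system.file("extdata", "specialty_costs_nonpmjay.csv",
                package = "blendedpay", mustWork = TRUE))
}

#' @rdname specialty_cost_table
#' @export
read_specialty_cost_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("specialty", "cost_per_admission") %in% names(d)))
    stopf("cost table needs columns specialty, cost_per_admission")
  if (any(d$cost_per_admission <= 0)) stopf("costs must be positive")
  stats::setNames(d$cost_per_admission, d$specialty)
}

#' Health-benefit-package tariff tables
#'
#' A tariff table maps HBP codes to a specialty, a bundled price per case
#' and the code's share of that specialty's annual insured case mix.
#' `tariff_table()` validates a data.frame; `read_tariff_table()` reads
#' one from CSV (columns `code`, `specialty`, `cost_per_case`,
#' `case_share`); `default_tariff_table()` returns the packaged synthetic
#' tariff set (the operational tariff list is programme data and must be
#' supplied by the user for real allocations).
#'
#' @param tariffs data.frame with the four columns above; case shares
#'   must sum to 1 within each specialty and costs must be positive.
#' @param path CSV path.
#' @return Validated data.frame of class `tariff_table`.
#' @export
tariff_table <- function(tariffs) {
  need <- c("code", "specialty", "cost_per_case", "case_share")
  missing_cols <- setdiff(need, names(tariffs))
  if (length(missing_cols))
    stopf("tariff table missing columns: %s",
          paste(missing_cols, collapse = ", "))
  if (any(tariffs$cost_per_case <= 0)) stopf("tariff costs must be positive")
  if (any(tariffs$case_share < 0)) stopf("case shares must be non-negative")
  sums <- tapply(tariffs$case_share, tariffs$specialty, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad))
    stopf("case shares must sum to 1 within each specialty: %s",
          paste(bad, collapse = ", "))
  structure(as.data.frame(tariffs), class = c("tariff_table", "data.frame"))
}

#' @rdname tariff_table
#' @export
read_tariff_table <- function(path) {
  tariff_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname tariff_table
#' @export
default_tariff_table <- function() {
  read_tariff_table(
    system.file("extdata", "hbp_tariffs_synthetic.csv",
                package = "blendedpay", mustWork = TRUE))
}

#' Economic cost of a benefit package from raw cost components
#'
#' Applies the health-system's economic-cost convention when building a
#' tariff from raw costing data: full recurrent cost plus a fraction
#' (default 20%) of the capital cost.
#'
#' @param recurrent annual recurrent cost per case (INR).
#' @param capital capital cost per case (INR).
#' @param capital_fraction fraction of capital included (default 0.20).
#' @return INR per case.
#' @export
hbp_economic_cost <- function(recurrent, capital, capital_fraction = 0.20) {
  if (any(recurrent < 0) || any(capital < 0)) stopf("costs must be non-negative")
  check_number(capital_fraction, "capital_fraction", 0, 1)
  recurrent + capital_fraction * capital
}

# case-mix weighted tariff price per insured admission, by specialty
tariff_mean_cost <- function(tariffs) {
  vapply(split(tariffs, tariffs$specialty),
         function(g) sum(g$cost_per_case * g$case_share), numeric(1))
}

#' Case-mix weighted cost per admission
#'
#' The volume-weighted mean per-admission cost over specialties:
#' \eqn{\sum_i n_i c_i / \sum_i n_i}. Always lies within the range of the
#' specialty costs used.
#'
#' @param cases named vector of admission counts (at least one positive).
#' @param costs named cost vector (e.g. [specialty_cost_table()]).
#' @return INR per admission.
#' @export
weighted_specialty_cost <- function(cases, costs) {
  if (all(cases == 0)) stopf("at least one admission count must be positive")
  if (any(cases < 0)) stopf("admission counts must be non-negative")
  missing_sp <- setdiff(names(cases)[cases > 0], names(costs))
  if (length(missing_sp))
    stopf("no cost for specialty: %s", paste(missing_sp, collapse = ", "))
  c_i <- costs[names(cases)]
  sum(cases * c_i) / sum(cases)
}

#' Annual case-based bundled payment for inpatient care
#'
#' For every specialty, the expected annual admissions are split into the
#' insured share (priced at the specialty's case-mix weighted tariff) and
#' the remainder (priced at the specialty's weighted cost for uninsured
#' admissions); the budget is the sum over specialties. Additive over
#' specialties and linear in beds.
#'
#' @param beds hospital bed count.
#' @param profiles a [specialty_profiles()] set.
#' @param tariffs a [tariff_table()].
#' @param nonpmjay_costs named cost vector (see [specialty_cost_table()]).
#' @return INR/year.
#' @export
inpatient_budget <- function(beds, profiles = default_specialty_profiles(),
                             tariffs = default_tariff_table(),
                             nonpmjay_costs = specialty_cost_table()) {
  adm <- expected_admissions(beds, profiles)
  tariff_cost <- tariff_mean_cost(tariffs)
  total <- 0
  for (i in seq_len(nrow(profiles))) {
    sp <- profiles$specialty[i]
    n_ins <- adm[[sp]] * profiles$pmjay_share[i]
    n_non <- adm[[sp]] - n_ins
    if (n_ins > 0) {
      if (!sp %in% names(tariff_cost))
        stopf("specialty missing from tariff table: %s", sp)
      total <- total + n_ins * tariff_cost[[sp]]
    }
    if (n_non > 0) {
      if (!sp %in% names(nonpmjay_costs))
        stopf("specialty missing from the uninsured cost table: %s", sp)
      total <- total + n_non * nonpmjay_costs[[sp]]
    }
  }
  total
}
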