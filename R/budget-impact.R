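# Budget impact: per-hospital allocation across the three payment
# streams, national/state rollups, comparison with actual expenditure,
# and currency conversion.

#' Construct a hospital payout record
#'
#' One hospital's annual payout under one scenario, as a one-row
#' data.frame with the three streams and their exact total.
#'
#' @param hospital_id,state identifiers.
#' @param scenario scenario label ("base", "iphs", "medical_college", ...).
#' @param outpatient,inpatient,indirect INR/year, each non-negative.
#' @param provenance semicolon-separated flags (e.g. placeholders used).
#' @return A one-row data.frame with `total = outpatient + inpatient +
#'   indirect`.
#' @export
hospital_payout <- function(hospital_id, state, scenario, outpatient,
                            inpatient, indirect, provenance = "") {
  comp <- c(outpatient = outpatient, inpatient = inpatient,
            indirect = indirect)
  if (any(!is.finite(comp)) || any(comp < 0))
    stopf("payout components must be finite and non-negative")
  data.frame(hospital_id = hospital_id, state = state, scenario = scenario,
             outpatient = outpatient, inpatient = inpatient,
             indirect = indirect, total = outpatient + inpatient + indirect,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Allocate the blended payment for one hospital
#'
#' Composes the three payment streams for a single hospital under the
#' requested scenario: outpatient from the risk-adjustment model,
#' inpatient from the case-based bundled payment, indirect from the
#' per-bed rate; scenario adjustments are delegated to [apply_iphs()] /
#' [apply_medical_college()].
#'
#' @param hospital one row of a facility table.
#' @param model a [risk_model()] for secondary outpatient care.
#' @param scenario "base", "iphs" or "medical_college".
#' @param config a [scenario_config()] carrying profiles, tariffs, cost
#'   tables and rates.
#' @param norms,salaries staffing inputs for the "iphs" scenario.
#' @return A [hospital_payout()] row.
#' @export
allocate <- function(hospital, model = canonical_outpatient_model(),
                     scenario = c("base", "iphs", "medical_college"),
                     config = scenario_config(),
                     norms = default_staffing_norms(),
                     salaries = default_salary_schedule()) {
  scenario <- match.arg(scenario)
  beds <- hospital$beds[1]
  op <- predict_outpatient_budget(
    model,
    hospital[1, c("city_tier", "population_lakhs", "imr", "pct_young_old",
                  "pct_public_utilization")],
    beds = beds, floor = config$outpatient_floor)
  ip <- if (beds > 0)
    inpatient_budget(beds, profiles_for_hospital(hospital, config$profiles),
                     config$tariffs, config$nonpmjay_costs) else 0
  ind <- indirect_budget(beds, config$rates$rate_base)
  prov <- if (identical(model$provenance, "synthetic_placeholder"))
    "outpatient_placeholder" else ""
  base <- hospital_payout(hospital$hospital_id[1], hospital$state[1], "base",
                          outpatient = op, inpatient = ip, indirect = ind,
                          provenance = prov)
  switch(scenario,
         base = base,
         iphs = apply_iphs(hospital, base, norms, salaries, config),
         medical_college = apply_medical_college(hospital, config))
}

#' Allocate payments for every hospital in a facility table
#'
#' Vectorized form of [allocate()].
#'
#' @param hospitals facility table (e.g. a national registry).
#' @inheritParams allocate
#' @return A payout data.frame with one row per hospital.
#' @export
allocate_payouts <- function(hospitals, model = canonical_outpatient_model(),
                             scenario = c("base", "iphs", "medical_college"),
                             config = scenario_config(),
                             norms = default_staffing_norms(),
                             salaries = default_salary_schedule()) {
  scenario <- match.arg(scenario)
  rows <- lapply(seq_len(nrow(hospitals)), function(i)
    allocate(hospitals[i, , drop = FALSE], model, scenario, config,
             norms, salaries))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll per-hospital payouts up to a national summary
#'
#' Mean, minimum, maximum and max/min ratio per stream and for the total;
#' stream shares (% of the national total); and per-state totals with
#' intra-state min/max/ratio.
#'
#' @param payouts payout data.frame from [allocate_payouts()].
#' @return Object of class `national_summary`: list with `n`, `streams`
#'   (data.frame: stream, mean, min, max, ratio), `shares` (named %,
#'   summing to 100), and `states` (data.frame with per-state n, total,
#'   min, max, ratio).
#' @export
national_rollup <- function(payouts) {
  if (!is.data.frame(payouts) || nrow(payouts) == 0L)
    stopf("payouts must be a non-empty data.frame")
  streams <- c("outpatient", "inpatient", "indirect", "total")
  stats_df <- do.call(rbind, lapply(streams, function(s) {
    v <- payouts[[s]]
    data.frame(stream = s, mean = mean(v), min = min(v), max = max(v),
               ratio = if (min(v) > 0) max(v) / min(v) else NA_real_)
  }))
  sums <- vapply(c("outpatient", "inpatient", "indirect"),
                 function(s) sum(payouts[[s]]), numeric(1))
  shares <- 100 * sums / sum(payouts$total)
  states <- do.call(rbind, lapply(split(payouts, payouts$state), function(g) {
    data.frame(state = g$state[1], n = nrow(g), total = sum(g$total),
               min = min(g$total), max = max(g$total),
               ratio = if (min(g$total) > 0) max(g$total) / min(g$total)
               else NA_real_)
  }))
  rownames(states) <- NULL
  structure(list(n = nrow(payouts), streams = stats_df, shares = shares,
                 states = states, total_sum = sum(payouts$total)),
            class = "national_summary")
}

#' @export
print.national_summary <- function(x, ...) {
  cat(sprintf("National payout summary over %d hospitals\n", x$n))
  s <- x$streams
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s mean %s  range [%s, %s]  ratio %s\n",
                s$stream[i],
                formatC(s$mean[i], format = "f", digits = 0, big.mark = ","),
                formatC(s$min[i], format = "f", digits = 0, big.mark = ","),
                formatC(s$max[i], format = "f", digits = 0, big.mark = ","),
                ifelse(is.na(s$ratio[i]), "NA",
                       formatC(s$ratio[i], format = "f", digits = 1))))
  cat(sprintf("  shares (%%): outpatient %.1f, inpatient %.1f, indirect %.1f\n",
              x$shares[["outpatient"]], x$shares[["inpatient"]],
              x$shares[["indirect"]]))
  invisible(x)
}

#' Compare proposed payouts with actual expenditure
#'
#' Per-hospital percentage deviation `(proposed - actual) / actual * 100`
#' over the hospitals present in both inputs. Hospitals with zero actual
#' expenditure are flagged and excluded from the percentages.
#'
#' @param proposed payout data.frame (needs `hospital_id`, `total`) or a
#'   named numeric vector of proposed totals.
#' @param actual named numeric vector, or data.frame with `hospital_id`
#'   and `actual`, of actual annual expenditure (INR/year).
#' @param band flag hospitals whose absolute deviation exceeds this many
#'   percent (default 20).
#' @return List with `table` (hospital_id, proposed, actual,
#'   deviation_pct, flagged), `summary` (min/max deviation, n, n_flagged)
#'   and `n_excluded` (zero-actual records).
#' @export
compare_with_actual <- function(proposed, actual, band = 20) {
  if (is.data.frame(proposed))
    proposed <- stats::setNames(proposed$total, proposed$hospital_id)
  if (is.data.frame(actual))
    actual <- stats::setNames(actual$actual, actual$hospital_id)
  ids <- intersect(names(proposed), names(actual))
  if (length(ids) == 0L) stopf("no overlapping hospital ids to compare")
  p <- proposed[ids]
  a <- actual[ids]
  zero <- a == 0
  if (any(zero))
    message(sprintf("compare_with_actual: excluded %d hospital(s) with zero actual expenditure",
                    sum(zero)))
  dev <- rep(NA_real_, length(ids))
  dev[!zero] <- (p[!zero] - a[!zero]) / a[!zero] * 100
  tab <- data.frame(hospital_id = ids, proposed = unname(p),
                    actual = unname(a), deviation_pct = unname(dev),
                    flagged = !is.na(dev) & abs(dev) > band)
  list(table = tab,
       summary = list(min = min(dev, na.rm = TRUE),
                      max = max(dev, na.rm = TRUE),
                      n = sum(!zero), n_flagged = sum(tab$flagged)),
       n_excluded = sum(zero))
}

#' Currency configuration and INR to USD conversion
#'
#' @param inr_per_usd exchange rate (default 82.54 INR per USD).
#' @return `currency_config()`: a list of class `currency_config`;
#'   `inr_to_usd()`: the unrounded USD amount (rounding is a
#'   display concern).
#' @export
currency_config <- function(inr_per_usd = 82.54) {
  check_number(inr_per_usd, "inr_per_usd", lower = 1e-12)
  structure(list(inr_per_usd = inr_per_usd), class = "currency_config")
}

#' @param amount INR amount(s).
#' @param fx a [currency_config()].
#' @rdname currency_config
#' @export
inr_to_usd <- function(amount, fx = currency_config()) {
  amount / fx$inr_per_usd
}

#' Percentage change between two budgets
#'
#' `(new - base) / base * 100`; the base must be positive.
#'
#' @param base,new INR amounts.
#' @return Percent change.
#' @export
percent_change <- function(base, new) {
  if (any(base <= 0)) stopf("base must be positive")
  (new - base) / base * 100
}

#' Write / read a payout table as CSV
#'
#' @param payouts payout data.frame.
#' @param path CSV path.
#' @return The path (writer, invisibly) / the payout data.frame (reader).
#' @export
write_payout_table <- function(payouts, path) {
  utils::write.csv(payouts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_payout_table
#' @export
read_payout_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
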