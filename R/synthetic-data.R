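# Synthetic facility-table generator: a small tier-stratified base sample
# emulating a multi-state hospital costing survey, expanded per tier with
# a multivariate normal distribution (MVND) to the analysis sample size,
# plus a national bed-registry fixture. Everything is deterministic for a
# fixed seed and fully overridable through the generator config.
#
# Tier covariate ranges deliberately overlap so that the tier dummies are
# not near-deterministic functions of the continuous covariates; the
# default design keeps every (generalized) variance inflation factor
# under 5, matching the assumption set of the outpatient model.

base_states <- function() {
  c("Himachal Pradesh", "Punjab", "Uttar Pradesh", "Rajasthan", "Gujarat",
    "Maharashtra", "Odisha", "Tamil Nadu", "Kerala")
}

registry_states <- function() {
  c(base_states(), "Andhra Pradesh", "Assam", "Bihar", "Chhattisgarh",
    "Goa", "Haryana", "Jharkhand", "Karnataka", "Madhya Pradesh",
    "Telangana", "Uttarakhand", "West Bengal")
}

#' Default per-tier covariate and cost-level ranges for the generator
#'
#' Packaged plausible ranges for Indian district hospitals: beds 100-700
#' overall (larger in bigger cities), IMR 15-60 (higher in smaller
#' cities), district population in lakhs, dependent-age share, and
#' public-sector utilization share. Cost levels are per-bed annual rates
#' (INR) for inpatient, indirect and capital stock. Only the relative
#' structure matters for testing; every entry can be overridden through
#' [generator_config()].
#'
#' @return Nested list: `$tier[[k]]` holds `min`/`max` per covariate for
#'   tier `k`; `$rates` holds `mean`/`sd` per-bed cost rates; `$staff_per_bed`
#'   holds nominal headcounts per bed; `$specialty_shares` the mean bed
#'   shares; `$share_concentration` the Dirichlet concentration.
#' @export
default_covariate_ranges <- function() {
  tier <- list(
    `1` = list(beds = c(300, 700), imr = c(15, 45),
               population_lakhs = c(20, 80), pct_young_old = c(12, 22),
               pct_public_utilization = c(20, 55)),
    `2` = list(beds = c(200, 550), imr = c(18, 52),
               population_lakhs = c(12, 60), pct_young_old = c(12, 22),
               pct_public_utilization = c(25, 62)),
    `3` = list(beds = c(150, 500), imr = c(22, 60),
               population_lakhs = c(8, 45), pct_young_old = c(12, 22),
               pct_public_utilization = c(28, 70)))
  rates <- list(ip_per_bed = c(mean = 700000, sd = 70000),
                indirect_per_bed = c(mean = 163969, sd = 20000),
                capital_per_bed = c(mean = 1500000, sd = 200000))
  shares <- stats::setNames(
    c(0.14, 0.26, 0.20, 0.07, 0.16, 0.06, 0.11), dh_specialties())
  list(tier = tier, rates = rates,
       staff_per_bed = c(doctor = 0.20, paramedical = 0.55, support = 0.30),
       staffing_fill = c(0.60, 1.05),
       specialty_shares = shares, share_concentration = 60)
}

#' Configuration for the synthetic facility generator
#'
#' @param n_base_per_tier named integer vector: base-sample size per city
#'   tier (default 5/9/13 = 27 hospitals, roughly proportional to the
#'   7/29/64 analysis composition).
#' @param expansion_counts named integer vector: per-tier sizes of the
#'   MVND-expanded analysis sample (default 7/29/64 = 100).
#' @param seed integer seed; every draw in the generator is scoped to it.
#' @param coefficient_truth [risk_model()] used to generate outpatient
#'   cost as linear predictor + Gaussian noise (default the published
#'   coefficient set).
#' @param noise_sd standard deviation (INR/year) of the additive Gaussian
#'   noise on outpatient cost. The default 2.2e7 puts the model's
#'   explanatory power near the R-squared the fitted specification is
#'   assumed to have (about 0.56) under the default covariate ranges.
#' @param covariance_shrinkage lambda in [0,1]: the per-tier covariance is
#'   shrunk as \eqn{\Sigma' = (1-\lambda)\Sigma + \lambda\,diag(\Sigma)}
#'   to guarantee positive semidefiniteness in small strata (default 0.1).
#' @param method "mvnd" (default) or "bootstrap" (resampling with
#'   replacement) for the expansion step.
#' @param op_cost_floor minimum generated outpatient cost (default 0).
#' @param ranges covariate/cost ranges, see [default_covariate_ranges()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_base_per_tier = c(`1` = 5L, `2` = 9L, `3` = 13L),
                             expansion_counts = c(`1` = 7L, `2` = 29L, `3` = 64L),
                             seed = 1L,
                             coefficient_truth = canonical_outpatient_model(),
                             noise_sd = 2.2e7,
                             covariance_shrinkage = 0.1,
                             method = c("mvnd", "bootstrap"),
                             op_cost_floor = 0,
                             ranges = default_covariate_ranges()) {
  method <- match.arg(method)
  if (is.null(names(n_base_per_tier))) names(n_base_per_tier) <- as.character(seq_along(n_base_per_tier))
  if (is.null(names(expansion_counts))) names(expansion_counts) <- as.character(seq_along(expansion_counts))
  if (any(n_base_per_tier < 0) || any(expansion_counts < 1))
    stopf("tier counts must be >= 0 (base) and >= 1 (expansion)")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(covariance_shrinkage, "covariance_shrinkage", 0, 1)
  if (!inherits(coefficient_truth, "risk_model"))
    stopf("coefficient_truth must be a risk_model")
  structure(
    list(n_base_per_tier = n_base_per_tier,
         expansion_counts = expansion_counts,
         seed = as.integer(seed),
         coefficient_truth = coefficient_truth,
         noise_sd = noise_sd,
         covariance_shrinkage = covariance_shrinkage,
         method = method,
         op_cost_floor = op_cost_floor,
         ranges = ranges),
    class = "generator_config")
}

# Dirichlet specialty shares around the configured means.
r_specialty_shares <- function(n, ranges) {
  alpha <- ranges$specialty_shares * ranges$share_concentration
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Generate the tier-stratified base facility sample
#'
#' Draws per-tier covariates from the configured ranges, generates annual
#' outpatient cost as the truth model's linear predictor plus
#' N(0, noise_sd^2) noise (floored at `op_cost_floor`), and derives
#' inpatient, indirect and capital costs, staffing and specialty bed
#' shares from per-bed rates. Emulates a small multi-state facility
#' costing survey.
#'
#' @param config a [generator_config()].
#' @return A facility table (data.frame), one row per hospital, passing
#'   [validate_facility_table()].
#' @export
generate_base_sample <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_tier <- config$n_base_per_tier
  if (sum(n_tier) < 1) stopf("base sample must have at least one hospital")
  withr::with_seed(config$seed, {
    rows <- lapply(names(n_tier), function(tier) {
      n <- n_tier[[tier]]
      if (n == 0L) return(NULL)
      rg <- config$ranges$tier[[tier]]
      if (is.null(rg)) stopf("no covariate ranges for tier %s", tier)
      runif_rg <- function(nm) stats::runif(n, rg[[nm]][1], rg[[nm]][2])
      data.frame(
        state = sample(base_states(), n, replace = TRUE),
        city_tier = as.integer(tier),
        population_lakhs = runif_rg("population_lakhs"),
        imr = runif_rg("imr"),
        pct_young_old = runif_rg("pct_young_old"),
        pct_public_utilization = runif_rg("pct_public_utilization"),
        beds = round(runif_rg("beds")))
    })
    out <- do.call(rbind, rows)
    n <- nrow(out)
    out$hospital_id <- sprintf("DH-%03d", seq_len(n))
    out$district_id <- sprintf("D-%03d", seq_len(n))
    rates <- config$ranges$rates
    per_bed <- function(r) pmax(0, stats::rnorm(n, r[["mean"]], r[["sd"]]))
    out$ip_cost <- out$beds * per_bed(rates$ip_per_bed)
    out$indirect_cost <- out$beds * per_bed(rates$indirect_per_bed)
    out$capital_cost <- out$beds * per_bed(rates$capital_per_bed)
    fill <- stats::runif(n, config$ranges$staffing_fill[1],
                         config$ranges$staffing_fill[2])
    for (cadre in staff_cadres()) {
      nominal <- config$ranges$staff_per_bed[[cadre]]
      out[[paste0("staff_", cadre)]] <- pmax(0, round(out$beds * nominal * fill))
    }
    shares <- r_specialty_shares(n, config$ranges)
    colnames(shares) <- share_cols()
    out <- cbind(out, as.data.frame(shares))
    lp <- predict_outpatient_budget(
      config$coefficient_truth,
      out[c("city_tier", "population_lakhs", "imr", "pct_young_old",
            "pct_public_utilization")],
      beds = out$beds, floor = -Inf)
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    out$op_cost <- pmax(config$op_cost_floor, lp + noise)
    out <- out[facility_columns()]
    rownames(out) <- NULL
    validate_facility_table(out)
  })
}

# numeric fields entering the per-tier MVND expansion
mvnd_fields <- function() {
  c("population_lakhs", "imr", "pct_young_old", "pct_public_utilization",
    "beds", "op_cost", "ip_cost", "indirect_cost", "capital_cost",
    staff_cols())
}

#' Expand a base facility sample per tier with a multivariate normal model
#'
#' For each tier present in `expansion_counts`, estimates the mean vector
#' and covariance matrix of the numeric facility fields from the base
#' records of that tier, shrinks the covariance as
#' \eqn{\Sigma' = (1-\lambda)\Sigma + \lambda\,diag(\Sigma)}, samples the
#' configured number of synthetic facilities, and clips samples back to
#' the physical bounds (counts >= 1 bed, non-negative costs and
#' headcounts, percentages in [0, 100]). Categorical fields (state,
#' specialty bed shares) are resampled from the tier's base records.
#'
#' With `method = "bootstrap"` the tier's base rows are instead resampled
#' with replacement.
#'
#' @param base facility table with at least 2 records in every tier being
#'   expanded (for "mvnd").
#' @param config a [generator_config()]; `expansion_counts`, `seed`,
#'   `covariance_shrinkage` and `method` are used.
#' @return A facility table with `sum(expansion_counts)` rows. The number
#'   of clipped values is attached as attribute `"n_clipped"`.
#' @export
expand_mvnd <- function(base, config) {
  stopifnot(inherits(config, "generator_config"))
  validate_facility_table(base)
  counts <- config$expansion_counts
  lambda <- config$covariance_shrinkage
  fields <- mvnd_fields()
  n_clipped <- 0L
  withr::with_seed(config$seed + 1L, {
    tiers <- names(counts)
    out <- lapply(tiers, function(tier) {
      m <- counts[[tier]]
      rows <- base[base$city_tier == as.integer(tier), , drop = FALSE]
      if (nrow(rows) == 0L)
        stopf("tier %s absent from the base sample", tier)
      if (config$method == "bootstrap") {
        idx <- sample.int(nrow(rows), m, replace = TRUE)
        return(rows[idx, , drop = FALSE])
      }
      if (nrow(rows) < 2L)
        stopf("need >= 2 base records in tier %s for the MVND expansion", tier)
      x <- as.matrix(rows[fields])
      mu <- colMeans(x)
      sigma <- stats::cov(x)
      sigma_s <- (1 - lambda) * sigma + lambda * diag(diag(sigma),
                                                      nrow = nrow(sigma))
      ev <- eigen(sigma_s, symmetric = TRUE, only.values = TRUE)$values
      if (lambda == 0 && min(ev) < 1e-8 * max(abs(ev), 1))
        stopf(paste("singular covariance in tier %s with covariance_shrinkage = 0;",
                    "increase covariance_shrinkage"), tier)
      smp <- MASS::mvrnorm(m, mu = mu, Sigma = sigma_s, tol = 1e-6)
      smp <- matrix(smp, nrow = m, dimnames = list(NULL, fields))
      # clip back to field invariants
      clip <- function(v, lo, hi = Inf) {
        bad <- v < lo | v > hi
        n_clipped <<- n_clipped + sum(bad)
        pmin(pmax(v, lo), hi)
      }
      smp[, "population_lakhs"] <- clip(smp[, "population_lakhs"], 0.1)
      smp[, "imr"] <- clip(smp[, "imr"], 0)
      smp[, "pct_young_old"] <- clip(smp[, "pct_young_old"], 0, 100)
      smp[, "pct_public_utilization"] <- clip(smp[, "pct_public_utilization"], 0, 100)
      smp[, "beds"] <- round(clip(smp[, "beds"], 1))
      for (col in c("op_cost", "ip_cost", "indirect_cost", "capital_cost"))
        smp[, col] <- clip(smp[, col], 0)
      for (col in staff_cols())
        smp[, col] <- round(clip(smp[, col], 0))
      donor <- rows[sample.int(nrow(rows), m, replace = TRUE), , drop = FALSE]
      new <- donor
      new[fields] <- as.data.frame(smp)
      new
    })
    out <- do.call(rbind, out)
    out$hospital_id <- sprintf("SIM-%03d", seq_len(nrow(out)))
    out$district_id <- sprintf("SD-%03d", seq_len(nrow(out)))
    rownames(out) <- NULL
    if (n_clipped > 0)
      message(sprintf("expand_mvnd: clipped %d sampled value(s) to bounds",
                      n_clipped))
    validate_facility_table(out)
    attr(out, "n_clipped") <- n_clipped
    out
  })
}

#' Generate a complete analysis sample (base + expansion)
#'
#' Convenience wrapper: [generate_base_sample()] followed by
#' [expand_mvnd()], yielding the tier-stratified analysis table (default
#' 7/29/64 = 100 facilities).
#'
#' @inheritParams generate_base_sample
#' @return A facility table of `sum(config$expansion_counts)` rows.
#' @export
generate_hospital_sample <- function(config = generator_config()) {
  expand_mvnd(generate_base_sample(config), config)
}

#' Generate a national district-hospital bed registry
#'
#' Stand-in for a national facility registry: per-state records with bed
#' counts, district indicators, staffing and capital stock for every
#' district hospital in scope (default 845). Facility cost columns are
#' `NA` — a registry records capacity, not observed costs; payouts for
#' registry hospitals are computed from the payment model, tariffs and
#' per-bed rates.
#'
#' @param n_hospitals number of hospitals (default 845).
#' @param seed integer seed.
#' @param ranges see [default_covariate_ranges()].
#' @param tier_prob sampling probabilities of tiers 1/2/3 (default
#'   0.07/0.29/0.64, the analysis-sample composition).
#' @return A facility table with `n_hospitals` rows (cost columns `NA`).
#' @export
generate_national_registry <- function(n_hospitals = 845L, seed = 1L,
                                       ranges = default_covariate_ranges(),
                                       tier_prob = c(0.07, 0.29, 0.64)) {
  if (n_hospitals < 1) stopf("n_hospitals must be >= 1")
  n <- as.integer(n_hospitals)
  withr::with_seed(as.integer(seed), {
    tier <- sample(1:3, n, replace = TRUE, prob = tier_prob)
    draw <- function(nm) {
      vapply(tier, function(k) {
        rg <- ranges$tier[[as.character(k)]][[nm]]
        stats::runif(1, rg[1], rg[2])
      }, numeric(1))
    }
    out <- data.frame(
      hospital_id = sprintf("NHR-%04d", seq_len(n)),
      state = sample(registry_states(), n, replace = TRUE),
      district_id = sprintf("ND-%04d", seq_len(n)),
      city_tier = tier,
      population_lakhs = draw("population_lakhs"),
      imr = draw("imr"),
      pct_young_old = draw("pct_young_old"),
      pct_public_utilization = draw("pct_public_utilization"),
      beds = round(draw("beds")),
      op_cost = NA_real_, ip_cost = NA_real_, indirect_cost = NA_real_)
    out$capital_cost <- out$beds *
      pmax(0, stats::rnorm(n, ranges$rates$capital_per_bed[["mean"]],
                           ranges$rates$capital_per_bed[["sd"]]))
    fill <- stats::runif(n, ranges$staffing_fill[1], ranges$staffing_fill[2])
    for (cadre in staff_cadres())
      out[[paste0("staff_", cadre)]] <-
        pmax(0, round(out$beds * ranges$staff_per_bed[[cadre]] * fill))
    shares <- r_specialty_shares(n, ranges)
    colnames(shares) <- share_cols()
    out <- cbind(out, as.data.frame(shares))
    out <- out[facility_columns()]
    validate_facility_table(out)
  })
}

#' Read / write a facility table as CSV
#'
#' One row per hospital; specialty bed shares as wide `share_*` columns.
#' The header is the column set documented in
#' [validate_facility_table()].
#'
#' @param hospitals facility table.
#' @param path CSV file path.
#' @return `write_facility_table()` returns `path` invisibly;
#'   `read_facility_table()` returns a validated facility table.
#' @export
write_facility_table <- function(hospitals, path) {
  validate_facility_table(hospitals)
  utils::write.csv(hospitals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_facility_table
#' @export
read_facility_table <- function(path) {
  validate_facility_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read / write a generator configuration as JSON
#'
#' @param config a [generator_config()].
#' @param path JSON file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a [generator_config()]. The
#'   covariate `ranges` are round-tripped as-is.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  ranges <- config$ranges
  # named atomic vectors must become JSON objects, not bare arrays
  ranges$rates <- lapply(ranges$rates, as.list)
  ranges$staff_per_bed <- as.list(ranges$staff_per_bed)
  ranges$specialty_shares <- as.list(ranges$specialty_shares)
  payload <- list(
    n_base_per_tier = as.list(config$n_base_per_tier),
    expansion_counts = as.list(config$expansion_counts),
    seed = config$seed,
    coefficient_truth = as.list(config$coefficient_truth$coefficients),
    noise_sd = config$noise_sd,
    covariance_shrinkage = config$covariance_shrinkage,
    method = config$method,
    op_cost_floor = config$op_cost_floor,
    ranges = ranges)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- do.call(risk_model, c(as.list(p$coefficient_truth),
                                 provenance = "user"))
  ranges <- p$ranges
  # restore numeric vectors lost in JSON round-trip
  ranges$tier <- lapply(ranges$tier, function(t) lapply(t, as.numeric))
  ranges$rates <- lapply(ranges$rates, function(r) unlist(r))
  ranges$staff_per_bed <- unlist(ranges$staff_per_bed)
  ranges$staffing_fill <- as.numeric(ranges$staffing_fill)
  ranges$specialty_shares <- unlist(ranges$specialty_shares)
  generator_config(
    n_base_per_tier = unlist(p$n_base_per_tier),
    expansion_counts = unlist(p$expansion_counts),
    seed = p$seed,
    coefficient_truth = truth,
    noise_sd = p$noise_sd,
    covariance_shrinkage = p$covariance_shrinkage,
    method = p$method,
    op_cost_floor = p$op_cost_floor,
    ranges = ranges)
}
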