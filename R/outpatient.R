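# Risk-adjusted global budget for outpatient care: the coefficient set,
# the OLS fit with its diagnostic battery, and the linear predictor that
# turns district indicators into an annual outpatient budget.

risk_model_betas <- function() {
  c("intercept", "tier2_offset", "tier3_offset", "beta_population",
    "beta_beds", "beta_imr", "beta_age", "beta_util")
}

#' Construct a risk-adjustment model for the outpatient global budget
#'
#' The outpatient budget for a hospital is the linear predictor
#' \deqn{B = \alpha + \delta_{tier} + \beta_{pop} x_{pop} + \beta_{beds}
#'  x_{beds} + \beta_{imr} x_{imr} + \beta_{age} x_{age} + \beta_{util}
#'  x_{util}}
#' where the tier offset is zero for tier-1 cities. Coefficients are in
#' INR per year per unit of the covariate: population in lakhs, beds in
#' bed counts, infant mortality rate (IMR) in deaths per 1,000 live
#' births, and the age-structure and public-utilization covariates in
#' percentage points.
#'
#' @param intercept,tier2_offset,tier3_offset INR/year; offsets relative
#'   to tier 1.
#' @param beta_population INR per lakh of district population.
#' @param beta_beds INR per bed.
#' @param beta_imr INR per IMR unit.
#' @param beta_age INR per percentage point of population under 5 or over
#'   60 years.
#' @param beta_util INR per percentage point of public-sector utilization.
#' @param r2,adj_r2 optional model fit statistics; `adj_r2` may not exceed
#'   `r2`.
#' @param se optional named numeric of standard errors (same names as the
#'   coefficients).
#' @param provenance character label recorded with the model (e.g.
#'   "fitted", "published", "synthetic_placeholder").
#' @return An object of class `risk_model`.
#' @seealso [canonical_outpatient_model()], [predict_outpatient_budget()],
#'   [fit_outpatient_model()]
#' @export
risk_model <- function(intercept, tier2_offset, tier3_offset,
                       beta_population, beta_beds, beta_imr, beta_age,
                       beta_util, r2 = NA_real_, adj_r2 = NA_real_,
                       se = NULL, provenance = "user") {
  coef <- c(intercept = intercept, tier2_offset = tier2_offset,
            tier3_offset = tier3_offset, beta_population = beta_population,
            beta_beds = beta_beds, beta_imr = beta_imr, beta_age = beta_age,
            beta_util = beta_util)
  if (any(!is.finite(coef))) stopf("all coefficients must be finite")
  if (!is.na(r2)) check_number(r2, "r2", 0, 1)
  if (!is.na(adj_r2) && !is.na(r2) && adj_r2 > r2 + 1e-12)
    stopf("adj_r2 cannot exceed r2")
  structure(
    list(coefficients = coef, r2 = r2, adj_r2 = adj_r2, se = se,
         provenance = provenance),
    class = "risk_model")
}

#' The published outpatient risk-adjustment coefficient set
#'
#' Returns the canonical coefficient vector of the outpatient
#' global-budget model for Indian district hospitals (tier-1 reference),
#' for allocation without refitting. Standard errors accompany the
#' coefficients; fit statistics are R-squared 0.5603 and adjusted
#' R-squared 0.5268.
#'
#' @return A [risk_model()] with provenance "published".
#' @export
canonical_outpatient_model <- function() {
  risk_model(
    intercept       =  75400000,
    tier2_offset    = -34300000,
    tier3_offset    = -51400000,
    beta_population =     60858,
    beta_beds       =     89121,
    beta_imr        =    565977,
    beta_age        =  -1673450,
    beta_util       =    -20079,
    r2 = 0.5603, adj_r2 = 0.5268,
    se = c(intercept = 32900000, tier2_offset = 10700000,
           tier3_offset = 11000000, beta_population = 126738,
           beta_beds = 16692, beta_imr = 171385, beta_age = 1227806,
           beta_util = 166842),
    provenance = "published")
}

#' Predict the annual outpatient global budget for a district hospital
#'
#' Evaluates the risk-adjustment linear predictor for one or more
#' districts. Negative predictions (possible for small tier-3 hospitals
#' with a high dependent-age share) are floored at `floor` with a warning.
#'
#' @param model a [risk_model()].
#' @param district data.frame (or coercible list) with columns
#'   `city_tier`, `population_lakhs`, `imr`, `pct_young_old`,
#'   `pct_public_utilization`.
#' @param beds bed counts (recycled against rows of `district`); `>= 0`.
#' @param floor minimum budget returned (default 0).
#' @return Numeric vector of INR/year.
#' @export
predict_outpatient_budget <- function(model, district, beds, floor = 0) {
  stopifnot(inherits(model, "risk_model"))
  district <- as.data.frame(district)
  need <- c("city_tier", "population_lakhs", "imr", "pct_young_old",
            "pct_public_utilization")
  missing_cols <- setdiff(need, names(district))
  if (length(missing_cols))
    stopf("district is missing columns: %s",
          paste(missing_cols, collapse = ", "))
  if (!all(district$city_tier %in% 1:3))
    stopf("unknown city tier: %s",
          paste(unique(setdiff(district$city_tier, 1:3)), collapse = ", "))
  if (any(beds < 0)) stopf("beds must be non-negative")
  b <- model$coefficients
  offset <- c(0, b[["tier2_offset"]], b[["tier3_offset"]])[district$city_tier]
  lp <- b[["intercept"]] + offset +
    b[["beta_population"]] * district$population_lakhs +
    b[["beta_beds"]] * beds +
    b[["beta_imr"]] * district$imr +
    b[["beta_age"]] * district$pct_young_old +
    b[["beta_util"]] * district$pct_public_utilization
  n_neg <- sum(lp < floor)
  if (n_neg > 0) {
    warning(sprintf(
      "%d predicted outpatient budget(s) below %s; floored", n_neg, floor),
      call. = FALSE)
    lp <- pmax(lp, floor)
  }
  unname(lp)
}

#' Fit the outpatient risk-adjustment model by ordinary least squares
#'
#' Regresses annual outpatient cost on the seven regressors (tier dummies
#' with tier 1 as reference, district population, bed strength, IMR,
#' dependent-age share, public-utilization share) and computes the
#' diagnostic battery used to justify the linear specification:
#' Lilliefors-corrected Kolmogorov–Smirnov normality tests of the
#' regressand and of the residuals, the (studentized) Breusch–Pagan
#' heteroscedasticity test, and variance inflation factors.
#'
#' @param hospitals a facility table (see [validate_facility_table()])
#'   with at least 10 rows; tiers 2 and 3 must both be represented.
#' @return An object of class `outpatient_fit`: a list with elements
#'   `model` (a [risk_model()] with fitted coefficients, provenance
#'   "fitted"), `diagnostics` (list with `ks_p_regressand`,
#'   `ks_p_residuals`, `bp_p`, `vif`, `r2`, `adj_r2`), and `fit` (the
#'   underlying `lm`).
#' @export
fit_outpatient_model <- function(hospitals) {
  validate_facility_table(hospitals)
  if (nrow(hospitals) < 10L)
    stopf("need at least 10 hospitals to fit the model, got %d",
          nrow(hospitals))
  if (!all(c(2L, 3L) %in% hospitals$city_tier))
    stopf("tiers 2 and 3 must both be represented (tier 1 is the reference)")
  if (any(is.na(hospitals$op_cost)))
    stopf("op_cost must be observed (non-NA) for all hospitals")
  d <- data.frame(
    op_cost = hospitals$op_cost,
    tier2 = as.numeric(hospitals$city_tier == 2L),
    tier3 = as.numeric(hospitals$city_tier == 3L),
    population_lakhs = hospitals$population_lakhs,
    beds = hospitals$beds,
    imr = hospitals$imr,
    pct_young_old = hospitals$pct_young_old,
    pct_public_utilization = hospitals$pct_public_utilization)
  x <- as.matrix(cbind(`(Intercept)` = 1, d[-1L]))
  if (nrow(x) < ncol(x))
    stopf("fewer rows (%d) than parameters (%d)", nrow(x), ncol(x))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[seq.int(qx$rank + 1L, ncol(x))]]
    stopf("singular design: column(s) %s are collinear with the others",
          paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(op_cost ~ tier2 + tier3 + population_lakhs + beds + imr +
                     pct_young_old + pct_public_utilization, data = d)
  s <- summary(fit)
  cf <- stats::coef(fit)
  se <- s$coefficients[, "Std. Error"]
  name_map <- c(`(Intercept)` = "intercept", tier2 = "tier2_offset",
                tier3 = "tier3_offset", population_lakhs = "beta_population",
                beds = "beta_beds", imr = "beta_imr",
                pct_young_old = "beta_age",
                pct_public_utilization = "beta_util")
  names(se) <- name_map[names(se)]
  model <- risk_model(
    intercept = cf[["(Intercept)"]], tier2_offset = cf[["tier2"]],
    tier3_offset = cf[["tier3"]], beta_population = cf[["population_lakhs"]],
    beta_beds = cf[["beds"]], beta_imr = cf[["imr"]],
    beta_age = cf[["pct_young_old"]],
    beta_util = cf[["pct_public_utilization"]],
    r2 = s$r.squared, adj_r2 = min(s$adj.r.squared, s$r.squared),
    se = se, provenance = "fitted")
  diagnostics <- outpatient_diagnostics(fit, d)
  structure(list(model = model, diagnostics = diagnostics, fit = fit),
            class = "outpatient_fit")
}

# Diagnostic battery on a fitted outpatient model. Normality is tested
# against a normal with estimated parameters (Lilliefors correction);
# with (near-)zero residual variance the tests are vacuous and p = 1.
# The city-tier dummies are one categorical term, so collinearity is
# measured with the generalized VIF, reported on the ordinary VIF scale
# as GVIF^(1/Df) so that the usual <5 / <10 thresholds apply.
outpatient_diagnostics <- function(fit, d) {
  resid <- stats::residuals(fit)
  safe_lillie <- function(x) {
    if (stats::sd(x) < sqrt(.Machine$double.eps) * max(1, mean(abs(x))))
      return(1)
    nortest::lillie.test(x)$p.value
  }
  bp_p <- tryCatch(lmtest::bptest(fit)$p.value,
                   error = function(e) NA_real_)
  vif <- tryCatch({
    df <- d
    df$tier <- factor(1L + df$tier2 + 2L * df$tier3)
    refit <- stats::lm(op_cost ~ tier + population_lakhs + beds + imr +
                         pct_young_old + pct_public_utilization, data = df)
    v <- car::vif(refit)
    if (is.matrix(v)) stats::setNames(v[, "GVIF^(1/(2*Df))"]^2, rownames(v))
    else v
  }, error = function(e) {
    stats::setNames(rep(NA_real_, length(stats::coef(fit)) - 1L),
                    names(stats::coef(fit))[-1L])
  })
  s <- summary(fit)
  list(ks_p_regressand = safe_lillie(d$op_cost),
       ks_p_residuals = safe_lillie(resid),
       bp_p = unname(bp_p),
       vif = vif,
       r2 = s$r.squared,
       adj_r2 = s$adj.r.squared)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Outpatient risk-adjustment model (", x$provenance, ")\n", sep = "")
  cat("Annual outpatient budget, INR/year; tier 1 is the reference.\n\n")
  b <- x$coefficients
  se <- x$se
  labels <- c(
    intercept = "Intercept",
    tier2_offset = "Type of city: tier 2",
    tier3_offset = "Type of city: tier 3",
    beta_population = "Population of the district (lakhs)",
    beta_beds = "Bed strength of district hospital",
    beta_imr = "Infant mortality rate",
    beta_age = "Population under 5 / above 60 (%)",
    beta_util = "Utilization of public health services (%)")
  for (nm in names(labels)) {
    line <- sprintf("  %-42s %15s", labels[[nm]],
                    formatC(b[[nm]], format = "f", digits = 0, big.mark = ","))
    if (!is.null(se) && nm %in% names(se)) {
      lo <- b[[nm]] - 1.96 * se[[nm]]
      hi <- b[[nm]] + 1.96 * se[[nm]]
      line <- paste0(line, sprintf(
        "  (SE %s; 95%% CI %s, %s)",
        formatC(se[[nm]], format = "f", digits = 0, big.mark = ","),
        formatC(lo, format = "f", digits = 0, big.mark = ","),
        formatC(hi, format = "f", digits = 0, big.mark = ",")))
    }
    cat(line, "\n")
  }
  if (!is.na(x$r2))
    cat(sprintf("  R-squared %.4f, adjusted R-squared %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

#' @export
print.outpatient_fit <- function(x, ...) {
  print(x$model)
  d <- x$diagnostics
  cat(sprintf(
    "\nDiagnostics: KS p (regressand) %.3f, KS p (residuals) %.3f, BP p %.3f\n",
    d$ks_p_regressand, d$ks_p_residuals, d$bp_p))
  cat("VIF:", paste(sprintf("%s %.2f", names(d$vif), d$vif),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a risk-adjustment model as JSON
#'
#' Round-trips the coefficient vector, fit statistics, standard errors and
#' provenance through a JSON document.
#'
#' @param model a [risk_model()].
#' @param path file path.
#' @return `write_risk_model()` returns `path` invisibly;
#'   `read_risk_model()` returns a [risk_model()].
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  payload <- list(coefficients = as.list(model$coefficients),
                  r2 = model$r2, adj_r2 = model$adj_r2,
                  se = if (!is.null(model$se)) as.list(model$se),
                  provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- payload$coefficients
  risk_model(
    intercept = co$intercept, tier2_offset = co$tier2_offset,
    tier3_offset = co$tier3_offset, beta_population = co$beta_population,
    beta_beds = co$beta_beds, beta_imr = co$beta_imr,
    beta_age = co$beta_age, beta_util = co$beta_util,
    r2 = payload$r2 %||% NA_real_, adj_r2 = payload$adj_r2 %||% NA_real_,
    se = if (!is.null(payload$se)) unlist(payload$se),
    provenance = payload$provenance %||% "user")
}
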