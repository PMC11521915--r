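# Outpatient risk-adjusted global budget: the published coefficient set,
# the linear predictor, the OLS fit with diagnostics, and model I/O.

test_that("the published coefficient set is exposed verbatim", {
  m <- canonical_outpatient_model()
  expect_equal(m$coefficients[["intercept"]], 75400000)
  expect_equal(m$coefficients[["tier2_offset"]], -34300000)
  expect_equal(m$coefficients[["tier3_offset"]], -51400000)
  expect_equal(m$coefficients[["beta_population"]], 60858)
  expect_equal(m$coefficients[["beta_beds"]], 89121)
  expect_equal(m$coefficients[["beta_imr"]], 565977)
  expect_equal(m$coefficients[["beta_age"]], -1673450)
  expect_equal(m$coefficients[["beta_util"]], -20079)
  expect_equal(m$r2, 0.5603)
  expect_equal(m$adj_r2, 0.5268)
})

test_that("the linear predictor matches term-by-term hand arithmetic", {
  m <- canonical_outpatient_model()
  # tier 1, all covariates zero: the intercept alone
  d0 <- data.frame(city_tier = 1L, population_lakhs = 0, imr = 0,
                   pct_young_old = 0, pct_public_utilization = 0)
  expect_equal(predict_outpatient_budget(m, d0, beds = 0), 75400000)
  # tier 3 worked example, computed term by term:
  # 75,400,000 - 51,400,000 + 60,858*20 + 89,121*300 + 565,977*40
  #   - 1,673,450*20 - 20,079*30 = 40,521,170
  d3 <- data.frame(city_tier = 3L, population_lakhs = 20, imr = 40,
                   pct_young_old = 20, pct_public_utilization = 30)
  expect_equal(predict_outpatient_budget(m, d3, beds = 300), 40521170)
  # tier offsets are exact differences at identical covariates
  d12 <- data.frame(city_tier = c(1L, 2L, 3L), population_lakhs = 25,
                    imr = 35, pct_young_old = 22, pct_public_utilization = 40)
  p <- predict_outpatient_budget(m, d12, beds = 200)
  expect_equal(p[2] - p[1], -34300000)
  expect_equal(p[3] - p[1], -51400000)
})

test_that("prediction is monotone in beds and IMR and ordered across tiers", {
  m <- canonical_outpatient_model()
  d <- data.frame(city_tier = 2L, population_lakhs = 30, imr = 30,
                  pct_young_old = 25, pct_public_utilization = 45)
  beds <- seq(50, 600, by = 50)
  p_beds <- predict_outpatient_budget(m, d[rep(1, length(beds)), ], beds)
  expect_true(all(diff(p_beds) > 0))
  imrs <- seq(10, 60, by = 5)
  d_imr <- d[rep(1, length(imrs)), ]
  d_imr$imr <- imrs
  expect_true(all(diff(predict_outpatient_budget(m, d_imr, 200)) > 0))
  d_t <- data.frame(city_tier = 1:3, population_lakhs = 30, imr = 30,
                    pct_young_old = 25, pct_public_utilization = 45)
  p_t <- predict_outpatient_budget(m, d_t, 200)
  expect_true(p_t[1] > p_t[2] && p_t[2] > p_t[3])
})

test_that("negative predictions are floored with a warning", {
  m <- canonical_outpatient_model()
  d <- data.frame(city_tier = 3L, population_lakhs = 1, imr = 0,
                  pct_young_old = 90, pct_public_utilization = 100)
  expect_warning(p <- predict_outpatient_budget(m, d, beds = 1), "floored")
  expect_equal(p, 0)
  expect_error(predict_outpatient_budget(
    m, data.frame(city_tier = 4L, population_lakhs = 1, imr = 1,
                  pct_young_old = 1, pct_public_utilization = 1), 10),
    "tier")
})

test_that("noiseless data is recovered exactly, and the fit is idempotent", {
  cfg <- small_config(seed = 13, noise_sd = 0)
  smp <- generate_base_sample(cfg)
  f <- suppressWarnings(fit_outpatient_model(smp))
  truth <- cfg$coefficient_truth$coefficients
  for (nm in names(truth))
    expect_equal(f$model$coefficients[[nm]], truth[[nm]],
                 tolerance = 1e-6)
  expect_equal(f$model$r2, 1, tolerance = 1e-6)

  # refitting the model on its own predictions reproduces it
  smp2 <- smp
  smp2$op_cost <- predict_outpatient_budget(
    f$model, smp[c("city_tier", "population_lakhs", "imr", "pct_young_old",
                   "pct_public_utilization")], smp$beds, floor = -Inf)
  f2 <- suppressWarnings(fit_outpatient_model(smp2))
  expect_equal(f2$model$coefficients, f$model$coefficients, tolerance = 1e-8)
})

test_that("degenerate designs raise informative errors", {
  smp <- generate_base_sample(small_config(seed = 17))
  dup <- smp
  dup$population_lakhs <- 2 * dup$beds  # exact linear dependence
  expect_error(fit_outpatient_model(dup), "singular|collinear")

  expect_error(fit_outpatient_model(smp[1:5, ]), "at least 10")

  only3 <- smp[smp$city_tier == 3L, ][rep(1:5, 3), ]
  expect_error(fit_outpatient_model(only3), "tiers 2 and 3")
})

test_that("diagnostics are well-formed on noisy fits", {
  f <- fit_outpatient_model(generate_base_sample(analysis_config(seed = 23)))
  d <- f$diagnostics
  expect_true(d$ks_p_regressand >= 0 && d$ks_p_regressand <= 1)
  expect_true(d$ks_p_residuals >= 0 && d$ks_p_residuals <= 1)
  expect_true(d$bp_p >= 0 && d$bp_p <= 1)
  expect_true(all(d$vif >= 1))
  expect_true(d$adj_r2 <= d$r2)
})

test_that("coefficient estimates stay within sampling error of the truth", {
  # across a handful of replicates, every coefficient within 3 SE
  truth <- canonical_outpatient_model()$coefficients
  n_ok <- 0L
  reps <- 25L
  for (s in seq_len(reps)) {
    f <- fit_outpatient_model(generate_base_sample(analysis_config(seed = 300 + s)))
    est <- f$model$coefficients
    se <- f$model$se
    ok <- all(abs(est[names(truth)] - truth) <= 3 * se[names(truth)])
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / reps, 0.9)
})

test_that("a risk model round-trips through JSON", {
  m <- canonical_outpatient_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  m2 <- read_risk_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$r2, m$r2)
  expect_equal(m2$se, m$se)
  expect_output(print(m2), "Intercept")
})
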