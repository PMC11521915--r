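# Synthetic facility generator: determinism, invariants, the zero-noise
# limit, the tier-stratified MVND expansion and the national registry.

test_that("generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 42)
  a <- generate_base_sample(cfg)
  b <- generate_base_sample(cfg)
  expect_identical(a, b)
  ea <- suppressMessages(expand_mvnd(a, cfg))
  eb <- suppressMessages(expand_mvnd(b, cfg))
  expect_equal(ea, eb)
  expect_identical(generate_national_registry(50, seed = 7),
                   generate_national_registry(50, seed = 7))
})

test_that("zero-noise outpatient cost equals the linear predictor exactly", {
  cfg <- small_config(seed = 5, noise_sd = 0)
  smp <- generate_base_sample(cfg)
  lp <- predict_outpatient_budget(
    cfg$coefficient_truth,
    smp[c("city_tier", "population_lakhs", "imr", "pct_young_old",
          "pct_public_utilization")],
    beds = smp$beds, floor = -Inf)
  expect_equal(smp$op_cost, pmax(0, lp), tolerance = 1e-12)
})

test_that("generated tables satisfy the facility invariants", {
  for (s in c(1, 2, 3)) {
    smp <- suppressMessages(generate_hospital_sample(small_config(seed = s)))
    expect_silent(validate_facility_table(smp))
    expect_true(all(rowSums(smp[paste0("share_", c(
      "paediatrics", "general_medicine", "obstetrics_gynaecology", "ent",
      "general_surgery", "ophthalmology", "orthopedics"))]) - 1 < 1e-9))
    expect_true(all(smp$op_cost >= 0 & smp$ip_cost >= 0 &
                      smp$indirect_cost >= 0))
    expect_true(all(smp$beds >= 1))
  }
})

test_that("MVND expansion reproduces the 7/29/64 analysis composition", {
  smp <- suppressMessages(generate_hospital_sample(small_config(seed = 11)))
  expect_equal(nrow(smp), 100L)
  expect_equal(as.vector(table(smp$city_tier)), c(7L, 29L, 64L))
})

test_that("expansion of identical records with full shrinkage is degenerate", {
  base <- do.call(rbind, lapply(1:3, function(i)
    make_hospital(id = paste0("B-", i), tier = 3L, beds = 250,
                  op_cost = 4e7, ip_cost = 2e8, indirect_cost = 4e7,
                  capital_cost = 3e8)))
  cfg <- generator_config(expansion_counts = c(`3` = 20L), seed = 1,
                          covariance_shrinkage = 1)
  out <- expand_mvnd(base, cfg)
  expect_equal(nrow(out), 20L)
  expect_true(all(out$beds == 250))
  expect_true(all(out$op_cost == 4e7))
  expect_true(all(out$imr == base$imr[1]))
})

test_that("singular covariance without shrinkage is an explicit error", {
  base <- make_facility_table(n = 5)
  base$city_tier <- 3L  # 5 records cannot span the numeric field space
  cfg <- generator_config(expansion_counts = c(`3` = 10L), seed = 1,
                          covariance_shrinkage = 0)
  expect_error(expand_mvnd(base, cfg), "shrinkage")
  # absent tier
  cfg2 <- generator_config(expansion_counts = c(`1` = 5L), seed = 1)
  expect_error(expand_mvnd(base, cfg2), "absent")
})

test_that("expansion preserves per-tier means within Monte-Carlo error", {
  base <- make_facility_table(n = 8)
  base$city_tier <- 3L
  cfg <- generator_config(expansion_counts = c(`3` = 10000L), seed = 21)
  out <- suppressMessages(expand_mvnd(base, cfg))
  for (col in c("beds", "imr", "population_lakhs", "op_cost", "ip_cost",
                "indirect_cost")) {
    se <- stats::sd(out[[col]]) / sqrt(nrow(out))
    expect_lt(abs(mean(out[[col]]) - mean(base[[col]])), 3 * se + 1e-9)
  }
})

test_that("bootstrap expansion resamples base records", {
  base <- make_facility_table(n = 9)
  base$city_tier <- rep(1:3, each = 3L)
  cfg <- generator_config(expansion_counts = c(`1` = 7L, `2` = 29L, `3` = 64L),
                          seed = 2, method = "bootstrap")
  out <- expand_mvnd(base, cfg)
  expect_equal(nrow(out), 100L)
  expect_true(all(out$beds %in% base$beds))
  expect_true(all(out$op_cost %in% base$op_cost))
})

test_that("national registry has the configured size and valid indicators", {
  reg <- generate_national_registry(seed = 3)
  expect_equal(nrow(reg), 845L)
  expect_silent(validate_facility_table(reg))
  expect_true(all(reg$imr >= 0 & reg$population_lakhs > 0))

  one <- generate_national_registry(1, seed = 4)
  expect_equal(nrow(one), 1L)

  expect_error(generate_national_registry(0), ">= 1")
})

test_that("facility tables and generator configs round-trip through disk", {
  smp <- generate_base_sample(small_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_facility_table(smp, path)
  back <- read_facility_table(path)
  expect_equal(back$op_cost, smp$op_cost)
  expect_equal(back$hospital_id, smp$hospital_id)

  cfg <- small_config(seed = 8, noise_sd = 1e6, covariance_shrinkage = 0.25)
  cpath <- withr::local_tempfile(fileext = ".json")
  write_generator_config(cfg, cpath)
  cfg2 <- read_generator_config(cpath)
  expect_equal(cfg2$noise_sd, cfg$noise_sd)
  expect_equal(cfg2$covariance_shrinkage, cfg$covariance_shrinkage)
  expect_equal(cfg2$coefficient_truth$coefficients,
               cfg$coefficient_truth$coefficients)
  expect_identical(generate_base_sample(cfg2)[c("beds", "imr")],
                   generate_base_sample(cfg)[c("beds", "imr")])
})
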