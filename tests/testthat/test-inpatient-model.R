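# Case-based bundled payment: admission throughput, weighted specialty
# costs and the composed inpatient budget.

test_that("expected admissions follow bed throughput arithmetic", {
  unit <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 365, bor = 1,
    pmjay_share = 0))
  expect_equal(unname(expected_admissions(1, unit)), 1.0)

  p <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 4, bor = 0.8,
    pmjay_share = 0))
  expect_equal(unname(expected_admissions(100, p)), 7300.0)

  empty <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 4, bor = 0,
    pmjay_share = 0))
  expect_equal(unname(expected_admissions(100, empty)), 0.0)

  expect_error(expected_admissions(100, data.frame(
    specialty = "x", bed_share = 1, alos = 0, bor = 1)), "alos")
})

test_that("weighted specialty cost is the volume-weighted mean", {
  costs <- specialty_cost_table()
  # degenerate weights return the specialty's packaged cost exactly
  expect_equal(weighted_specialty_cost(c(Paediatrics = 10), costs), 10415)
  # equal counts for the cheapest and dearest specialties
  expect_equal(weighted_specialty_cost(
    c(Ophthalmology = 5, `Ear Nose and Throat` = 5), costs), 11985.5)
  # any non-negative weights stay within the cost range
  withr::with_seed(1, {
    for (i in 1:50) {
      w <- stats::setNames(stats::runif(7, 0, 100), names(costs))
      v <- weighted_specialty_cost(w, costs)
      expect_true(v >= 9867 && v <= 14104)
    }
  })
  expect_error(weighted_specialty_cost(stats::setNames(rep(0, 7),
                                                       names(costs)), costs),
               "positive")
})

test_that("inpatient budget composes tariffed and uninsured admissions", {
  costs <- specialty_cost_table()
  tariffs <- default_tariff_table()
  profiles <- default_specialty_profiles()

  expect_equal(inpatient_budget(0, profiles, tariffs, costs), 0)

  # a single uninsured specialty prices every admission at its weighted cost
  gm <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 3.65, bor = 1,
    pmjay_share = 0))
  expect_equal(inpatient_budget(1, gm, tariffs, costs), 100 * 10481)

  # fully insured with a single package of cost c prices n * c
  one_hbp <- tariff_table(data.frame(
    code = "HBP-X", specialty = "General Medicine", cost_per_case = 12000,
    case_share = 1))
  ins <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 3.65, bor = 1,
    pmjay_share = 1))
  expect_equal(inpatient_budget(1, ins, one_hbp, costs), 100 * 12000)

  # a specialty absent from both price sources is named in the error
  bad <- specialty_profiles(data.frame(
    specialty = "Cardiology", bed_share = 1, alos = 4, bor = 0.8,
    pmjay_share = 0))
  expect_error(inpatient_budget(100, bad, tariffs, costs), "Cardiology")
})

test_that("inpatient budget is homogeneous in beds and monotone in prices", {
  costs <- specialty_cost_table()
  tariffs <- default_tariff_table()
  profiles <- default_specialty_profiles()
  b1 <- inpatient_budget(250, profiles, tariffs, costs)
  expect_equal(inpatient_budget(500, profiles, tariffs, costs), 2 * b1,
               tolerance = 1e-12)
  # monotone in occupancy
  hi_bor <- profiles
  hi_bor$bor <- pmin(1, profiles$bor + 0.1)
  expect_gt(inpatient_budget(250, hi_bor, tariffs, costs), b1)
  # monotone in tariff and uninsured prices
  dearer <- tariffs
  dearer$cost_per_case <- tariffs$cost_per_case * 1.2
  expect_gt(inpatient_budget(250, profiles, tariff_table(dearer), costs), b1)
  expect_gt(inpatient_budget(250, profiles, tariffs, costs * 1.2), b1)
})

test_that("budget equals a per-admission enumeration oracle", {
  costs <- specialty_cost_table()
  # integer-count instance: 100 beds, bor .8, alos 4 -> 7300 admissions;
  # 40% insured -> 2920 split 1460/876/584 across three packages
  tariffs <- tariff_table(data.frame(
    code = c("A", "B", "C"), specialty = "General Medicine",
    cost_per_case = c(9000, 12000, 15000), case_share = c(0.5, 0.3, 0.2)))
  p <- specialty_profiles(data.frame(
    specialty = "General Medicine", bed_share = 1, alos = 4, bor = 0.8,
    pmjay_share = 0.4))
  oracle <- sum(rep(c(9000, 12000, 15000), c(1460, 876, 584))) +
    4380 * 10481
  expect_equal(inpatient_budget(100, p, tariffs, costs), oracle,
               tolerance = 1e-6)
})

test_that("tariff machinery validates and prices economic costs", {
  expect_error(tariff_table(data.frame(
    code = "X", specialty = "Paediatrics", cost_per_case = 100,
    case_share = 0.5)), "sum to 1")
  expect_equal(hbp_economic_cost(10000, 5000), 11000)
  expect_equal(hbp_economic_cost(10000, 5000, capital_fraction = 0), 10000)
  # hospital-specific bed shares are substituted and renormalized
  h <- make_hospital(shares = c(0.5, 0.5, 0, 0, 0, 0, 0))
  pf <- profiles_for_hospital(h, default_specialty_profiles())
  expect_equal(pf$bed_share[pf$specialty == "Paediatrics"], 0.5)
  expect_equal(sum(pf$bed_share), 1)
})
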