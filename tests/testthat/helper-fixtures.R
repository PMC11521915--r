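# Fixtures built in code: a minimal hand-specified facility row and a
# small generator configuration used across the unit tests.

make_hospital <- function(id = "H-1", state = "Punjab", tier = 3L,
                          population = 20, imr = 40, age = 20, util = 30,
                          beds = 300, op_cost = NA_real_, ip_cost = NA_real_,
                          indirect_cost = NA_real_, capital_cost = 0,
                          doctors = 60, paramedical = 165, support = 90,
                          shares = NULL) {
  if (is.null(shares))
    shares <- c(0.14, 0.26, 0.20, 0.07, 0.16, 0.06, 0.11)
  row <- data.frame(
    hospital_id = id, state = state, district_id = paste0("D-", id),
    city_tier = as.integer(tier), population_lakhs = population, imr = imr,
    pct_young_old = age, pct_public_utilization = util, beds = beds,
    op_cost = op_cost, ip_cost = ip_cost, indirect_cost = indirect_cost,
    capital_cost = capital_cost, staff_doctor = doctors,
    staff_paramedical = paramedical, staff_support = support)
  share_df <- as.data.frame(as.list(shares))
  names(share_df) <- paste0("share_", c(
    "paediatrics", "general_medicine", "obstetrics_gynaecology", "ent",
    "general_surgery", "ophthalmology", "orthopedics"))
  cbind(row, share_df)
}

make_facility_table <- function(n = 12, seed = 99) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      make_hospital(id = sprintf("H-%02d", i),
                    tier = sample(1:3, 1),
                    population = runif(1, 10, 60),
                    imr = runif(1, 20, 55),
                    age = runif(1, 18, 30),
                    util = runif(1, 25, 65),
                    beds = sample(100:600, 1),
                    op_cost = runif(1, 2e7, 9e7),
                    ip_cost = runif(1, 1e8, 4e8),
                    indirect_cost = runif(1, 1e7, 9e7),
                    capital_cost = runif(1, 1e8, 9e8))
    })
    do.call(rbind, rows)
  })
}

small_config <- function(seed = 1, ...) {
  generator_config(n_base_per_tier = c(`1` = 4L, `2` = 6L, `3` = 8L),
                   expansion_counts = c(`1` = 7L, `2` = 29L, `3` = 64L),
                   seed = seed, ...)
}

# the analysis-scale design: 100 directly generated facilities, 7/29/64
analysis_config <- function(seed = 1, ...) {
  generator_config(n_base_per_tier = c(`1` = 7L, `2` = 29L, `3` = 64L),
                   seed = seed, ...)
}
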