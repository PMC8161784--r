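# Base-case societal cost-savings model.

test_that("visits saved follows the per-patient rate times cohort size", {
  v <- visits_saved(cost_parameters())
  expect_equal(v$unrounded, 1.06 * 350)
  expect_equal(v$rounded, 371)
  expect_equal(visits_saved(cost_parameters(visits_saved_per_patient = 0))$rounded, 0)
  # the rate equals the difference of the published arm visit means
  v2 <- visits_saved(cost_parameters(visits_saved_per_patient = 2.68 - 1.62))
  expect_equal(v2$rounded, 371)
})

test_that("base-case breakdown reproduces the published table to the dollar", {
  b <- total_savings(cost_parameters())
  expect_equal(b$visits_saved_rounded, 371)
  expect_equal(b$caregiver_visits_saved, 463.75)
  expect_equal(b$parking_savings, 2226)
  expect_equal(b$travel_savings, 21941)
  expect_equal(b$out_of_pocket_total, 24167)
  expect_equal(b$out_of_pocket_per_patient, 69)
  expect_equal(b$patient_productivity_savings, 6379)
  expect_equal(b$caregiver_productivity_savings, 17335)
  expect_equal(b$productivity_total, 23714)
  expect_equal(b$admin_savings, 508)
  expect_equal(b$grand_total, 48389)
  expect_equal(b$per_patient, 138)
})

test_that("caregiver visits stay unrounded inside the productivity formula", {
  # rounding 463.75 to 464 before multiplying would give 17,345, not 17,335
  p <- productivity_savings(cost_parameters())
  expect_equal(p$caregiver_visits, 463.75)
  expect_equal(p$caregiver_cad, 17335)
  rounded_first <- mdcecon::round_half_away(
    464 * 0.5 * 2.53 * 29.55)
  expect_equal(rounded_first, 17345)
})

test_that("distance-mode travel uses km times allowance rate", {
  p <- cost_parameters(travel_cost_per_visit = NULL,
                       return_distance_km = 102, travel_rate_per_km = 0.58)
  expect_equal(p$travel_cost_per_visit, 59.16)
  oop <- out_of_pocket_savings(p)
  expect_equal(oop$travel_cad, 21948)
  expect_error(cost_parameters(travel_cost_per_visit = 59.14,
                               return_distance_km = 102,
                               travel_rate_per_km = 0.58),
               "not both")
  expect_error(cost_parameters(travel_cost_per_visit = NULL,
                               return_distance_km = 102),
               "distance mode")
})

test_that("unit and zero edge cases", {
  z <- total_savings(cost_parameters(parking_cost_per_visit = 0,
                                     travel_cost_per_visit = 0,
                                     wage_per_hour = 0,
                                     admin_cost_per_visit = 0))
  expect_equal(z$grand_total, 0)
  expect_equal(z$unrounded$grand_total, 0)

  z2 <- out_of_pocket_savings(cost_parameters(visits_saved_per_patient = 0))
  expect_equal(c(z2$parking_cad, z2$travel_cad, z2$total_cad,
                 z2$per_patient_cad), c(0, 0, 0, 0))

  # one visit, one patient under 65, one hour: patient component = wage
  p <- cost_parameters(visits_saved_per_patient = 1, n_patients = 1,
                       prop_under65 = 1, clinic_visit_hours = 1,
                       time_forgone_hours = 0)
  expect_equal(productivity_savings(p)$patient, 29.55)

  a <- admin_savings(cost_parameters(visits_saved_per_patient = 1,
                                     n_patients = 1))
  expect_equal(a$total, 1.37)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(cost_parameters(prop_under65 = 1.2), "prop_under65")
  expect_error(cost_parameters(wage_per_hour = -1), "wage_per_hour")
  expect_error(cost_parameters(n_patients = 0), "n_patients")
})

test_that("savings are linear in the visits-saved rate", {
  # at a scale where the rounded visit count doubles exactly
  p1 <- cost_parameters(visits_saved_per_patient = 1)
  p2 <- cost_parameters(visits_saved_per_patient = 2)
  b1 <- total_savings(p1); b2 <- total_savings(p2)
  expect_equal(b2$unrounded$grand_total, 2 * b1$unrounded$grand_total,
               tolerance = 1e-12)
  for (f in c("parking", "travel", "patient_productivity",
              "caregiver_productivity", "admin"))
    expect_equal(b2$unrounded[[f]], 2 * b1$unrounded[[f]], tolerance = 1e-12)
})

test_that("extrapolation scales the unrounded per-patient total", {
  b <- total_savings(cost_parameters())
  e <- extrapolate_savings(b, 585)
  expect_equal(e, b$unrounded$grand_total / 350 * 585)
  # agrees with the published three-year figure within 0.01%
  expect_lt(abs(e - 80882.10) / 80882.10, 1e-4)
  expect_equal(extrapolate_savings(b, 350), b$unrounded$grand_total)
  expect_equal(extrapolate_savings(b, 0), 0)
})

test_that("per-patient enumeration reproduces the aggregate formulas", {
  # distribute the 371 saved visits over 350 patients, each carrying the
  # cohort-mean distance, caregiver count and an under-65 weight, and sum
  # per-patient dollar amounts: must match the closed-form aggregate to <1 CAD
  p <- cost_parameters()
  visits_i <- mdcecon::largest_remainder(371, rep(1, 350))
  expect_equal(sum(visits_i), 371)
  t_h <- p$clinic_visit_hours + p$time_forgone_hours
  per_patient <- visits_i * (p$parking_cost_per_visit +
    p$travel_cost_per_visit +
    p$prop_under65 * t_h * p$wage_per_hour +
    p$caregivers_per_visit * p$caregiver_employment_prop * t_h *
      p$wage_per_hour +
    p$admin_cost_per_visit)
  b <- total_savings(p)
  expect_lt(abs(sum(per_patient) - b$unrounded$grand_total), 1)
})

test_that("breakdown serializes to Table-shaped CSV and JSON", {
  b <- total_savings(cost_parameters())
  f <- withr::local_tempfile(fileext = ".csv")
  write_cost_breakdown(b, f)
  tab <- read.csv(f)
  expect_equal(tab$value[tab$item == "Total savings"], 48389)
  j <- withr::local_tempfile(fileext = ".json")
  write_cost_breakdown(b, j)
  back <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(back$grand_total, 48389)
  expect_equal(back$unrounded$grand_total, b$unrounded$grand_total)
})

test_that("packaged parameter file equals the base case", {
  p <- read_cost_parameters(system.file("extdata", "cost_parameters.yaml",
                                        package = "mdcecon"))
  expect_equal(total_savings(p)$grand_total, 48389)
})
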