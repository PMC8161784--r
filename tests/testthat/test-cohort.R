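# Synthetic cohort generator: calibration, determinism, validation, I/O.

test_that("calibrated generation reproduces the published cohort marginals", {
  coh <- default_calibrated_cohort()
  expect_equal(nrow(coh), 428)
  expect_equal(sum(coh$arm == "traditional"), 78)
  expect_equal(sum(coh$arm == "mdc"), 350)

  md <- coh[coh$arm == "mdc", ]
  expect_equal(unname(table(factor(md$stage, levels = c("1","2","3","4","undetermined")))),
               c(109, 26, 69, 143, 3), ignore_attr = TRUE)
  expect_equal(sum(md$diagnosis == "NSCLC"), 260)
  expect_equal(sum(md$diagnosis == "SCLC"), 45)
  expect_equal(sum(md$diagnosis == "presumed_LC"), 45)

  tr <- coh[coh$arm == "traditional", ]
  expect_equal(unname(table(factor(tr$stage, levels = c("1","2","3","4","undetermined")))),
               c(24, 6, 14, 29, 5), ignore_attr = TRUE)

  # under-65 fraction enforced exactly (79/350 MDC)
  expect_equal(sum(md$age_years < 65), 79)
  # distance mean matched exactly
  expect_equal(mean(md$return_distance_km), 102.0, tolerance = 1e-12)
  # caregivers in range with mean near 1.25
  expect_true(all(coh$caregivers %in% 1:4))
  expect_equal(mean(md$caregivers), 1.25, tolerance = 0.005)
  # EBUS restricted to stage 2/3 and counts match uptake proportions
  expect_true(all(coh$stage[coh$ebus_performed] %in% c("2", "3")))
  expect_equal(sum(tr$ebus_performed), 3)
  expect_equal(sum(md$ebus_performed), 57)
})

test_that("calibrated per-stage visit means hit spec targets within 1/(2n)", {
  coh <- default_calibrated_cohort()
  spec <- default_cohort_spec()
  for (arm in c("traditional", "mdc")) {
    for (s in c("1", "2", "3", "4")) {
      d <- coh[coh$arm == arm & coh$stage == s, ]
      target <- spec$visit_means[[arm]][[s]]
      expect_lt(abs(mean(d$oncology_visits) - target), 1 / (2 * nrow(d)) + 1e-12,
                label = sprintf("visit mean, %s stage %s", arm, s))
    }
    # arm-level means include undetermined-stage patients
    d <- coh[coh$arm == arm, ]
    target <- if (arm == "mdc") 1.62 else 2.68
    expect_lt(abs(mean(d$oncology_visits) - target), 1 / (2 * nrow(d)) + 1e-12)
  }
})

test_that("generation is deterministic in (spec, seed)", {
  spec <- default_cohort_spec()
  expect_identical(generate_cohort(spec, 42, calibrated = TRUE),
                   generate_cohort(spec, 42, calibrated = TRUE))
  expect_identical(generate_cohort(spec, 42, calibrated = FALSE),
                   generate_cohort(spec, 42, calibrated = FALSE))
  # different seeds give different sampled cohorts
  expect_false(identical(generate_cohort(spec, 1, calibrated = FALSE),
                         generate_cohort(spec, 2, calibrated = FALSE)))
  # generation does not disturb the session RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_cohort(spec, 5, calibrated = FALSE))
  expect_identical(runif(3), before)
})

test_that("sampled generation recovers spec means in expectation", {
  spec <- default_cohort_spec()
  means <- vapply(1:100, function(s) {
    coh <- generate_cohort(spec, seed = s, calibrated = FALSE)
    mean(coh$oncology_visits[coh$arm == "mdc" & coh$stage == "4"])
  }, numeric(1))
  # shifted-Poisson model: mean 1 + (1.29 - 1); SE over 100 seeds
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1.29), 3 * se + 0.02)
})

test_that("summarize_cohort recovers the calibrated marginals", {
  s <- summarize_cohort(default_calibrated_cohort())
  expect_equal(s$mdc$n, 350)
  expect_equal(unname(s$mdc$stage_counts[["1"]]), 109)
  expect_equal(unname(s$mdc$diagnosis_counts[["NSCLC"]]), 260)
  expect_equal(s$mdc$mean_distance_km, 102.0, tolerance = 1e-9)
  expect_equal(s$mdc$n_under65, 79)
  expect_error(summarize_cohort(data.frame()), "empty")
})

test_that("single-patient summaries degenerate correctly", {
  coh <- tiny_cohort()[1, ]
  s <- summarize_cohort(coh)
  expect_equal(s[[1]]$n, 1)
  expect_equal(s[[1]]$mean_age, coh$age_years)
  expect_true(all(unlist(s[[1]]$stage_counts) %in% c(0, 1)))
})

test_that("invalid specifications fail naming the offending field", {
  expect_error(cohort_spec(n = c(traditional = 0, mdc = 350)),
               "n\\[traditional\\]")
  bad <- list(traditional = c(`1` = 0.5, `2` = 0.2, `3` = 0.2, `4` = 0.2,
                              undetermined = 0.1),
              mdc = default_cohort_spec()$stage_props$mdc)
  expect_error(cohort_spec(stage_props = bad), "stage_props")
  expect_error(cohort_spec(ebus_prob = c(traditional = 1.5, mdc = 0.6)),
               "ebus_prob")
  expect_error(cohort_spec(caregiver_probs = c(0.9, 0.2, 0, -0.1)),
               "caregiver_probs")
})

test_that("cohort CSV round-trips byte-identically on re-write", {
  coh <- tiny_cohort()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f1)
  back <- read_cohort(f1)
  expect_equal(back$oncology_visits, coh$oncology_visits)
  expect_equal(back$ebus_performed, coh$ebus_performed)
  expect_equal(back$treatments, coh$treatments)
  write_cohort(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("packaged default spec file equals the in-code default", {
  path <- system.file("extdata", "cohort_spec.yaml", package = "mdcecon")
  spec <- read_cohort_spec(path)
  expect_identical(generate_cohort(spec, 3),
                   generate_cohort(default_cohort_spec(), 3))
})
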