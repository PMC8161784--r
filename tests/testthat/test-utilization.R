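# Resource-utilization comparisons: means, two-sample tests, report table.

test_that("mean_utilization computes stratified arithmetic means", {
  coh <- default_calibrated_cohort()
  m <- mean_utilization(coh, "traditional", "oncology_visits")
  expect_equal(m$n, 78)
  expect_equal(m$mean, 2.68, tolerance = 1 / (2 * 78) / 2.68)
  m <- mean_utilization(coh, "mdc", "oncology_visits", stage = "3")
  expect_equal(m$n, 69)
  expect_equal(m$mean, 2.03, tolerance = 1 / (2 * 69) / 2.03)
  m <- mean_utilization(coh, "mdc", "biopsies")
  # target sum 1.17 * 350 = 409.5 sits exactly on the allocation bound
  expect_lte(abs(m$mean - 1.17), 1 / (2 * 350) + 1e-12)

  tiny <- tiny_cohort()
  tiny$oncology_visits[tiny$arm == "traditional"] <- c(1L, 2L, 2L, 1L, 1L, 2L)
  m <- mean_utilization(tiny, "traditional", "oncology_visits")
  expect_equal(m$mean, 1.5)
  expect_error(mean_utilization(coh, "traditional", "oncology_visits",
                                stage = "undetermined"), "undetermined")
})

test_that("compare_means matches the closed-form Welch statistic", {
  # hand-computed: equal variances 2.5, n = 5 each -> t = -1, df = 8
  cmp <- compare_means(1:5, 2:6, "welch_t")
  expect_equal(cmp$statistic, -1, tolerance = 1e-12)
  expect_equal(cmp$df, 8, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(-1, 8), tolerance = 1e-12)
  expect_equal(cmp$difference, -1)

  # identical groups: zero difference, p = 1
  cmp <- compare_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)

  # near-complete separation
  cmp <- compare_means(c(0, 0, 0, 0.0001), c(10, 10, 10, 10.0001))
  expect_lt(cmp$p_value, 0.001)

  # student variant agrees with Welch for balanced equal-variance groups
  cmp2 <- compare_means(1:5, 2:6, "student_t")
  expect_equal(cmp2$statistic, -1, tolerance = 1e-12)

  expect_error(compare_means(1, c(1, 2)), "at least 2")
  expect_error(compare_means(c(2, 2), c(3, 3)), "zero variance")
})

test_that("compare_proportions reproduces the EBUS-uptake comparison", {
  cmp <- compare_proportions(3, 20, 57, 95, method = "chi_squared")
  expect_equal(unname(cmp$values), c(15.0, 60.0))
  expect_equal(cmp$df, 1)
  expect_equal(cmp$statistic, 13.37, tolerance = 0.01)
  expect_lt(cmp$p_value, 0.001)

  sym <- compare_proportions(57, 95, 3, 20, method = "chi_squared")
  expect_equal(sym$p_value, cmp$p_value)
  expect_equal(sym$difference, -cmp$difference)

  eq <- compare_proportions(5, 10, 5, 10)
  expect_equal(eq$difference, 0)
  expect_equal(eq$p_value, 1)

  # auto-switch to Fisher's exact when an expected count is below 5
  small <- compare_proportions(1, 8, 6, 9, method = "auto")
  expect_equal(small$method, "fisher_exact")
  big <- compare_proportions(30, 100, 45, 100, method = "auto")
  expect_equal(big$method, "chi_squared")

  expect_error(compare_proportions(5, 4, 1, 10), "successes")
  expect_error(compare_proportions(1, 0, 1, 10), "n")
})

test_that("chi-squared p agrees with a margin-conditioned permutation null", {
  cases <- list(c(30, 100, 45, 100), c(168, 400, 150, 400),
                c(250, 600, 350, 800))
  for (cs in cases) {
    cmp <- compare_proportions(cs[1], cs[2], cs[3], cs[4],
                               method = "chi_squared")
    p_perm <- permutation_prop_p(cs[1], cs[2], cs[3], cs[4], B = 10000)
    se <- sqrt(max(p_perm * (1 - p_perm), 1e-4) / 10000)
    expect_lt(abs(cmp$p_value - p_perm), 3 * se + 0.005,
              label = paste("table", paste(cs, collapse = "/")))
  }
})

test_that("compare_anova is a one-way F test over k groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(8, 9, 10, 11))
  res <- compare_anova(g)
  ref <- stats::oneway.test(
    c(g$a, g$b, g$c) ~ factor(rep(1:3, each = 4)), var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_error(compare_anova(list(1:3)), "two groups")
})

test_that("utilization_report reproduces the published comparison table", {
  rep <- utilization_report(default_calibrated_cohort())
  row <- function(lbl) rep[rep$label == lbl, ]
  all <- row("Mean oncology visits, all patients")
  expect_equal(all$traditional, 2.68, tolerance = 0.01 / 2.68)
  expect_equal(all$mdc, 1.62, tolerance = 0.01 / 1.62)
  expect_lt(all$p_value, 0.001)

  st4 <- row("Stage 4 receiving ST")
  expect_equal(st4$traditional, 100 * 11 / 29, tolerance = 1e-9)
  expect_equal(st4$mdc, 100 * 57 / 143, tolerance = 1e-9)

  ebus <- row("EBUS-TBNA for stage 2/3 patients")
  expect_equal(ebus$traditional, 15.0)
  expect_equal(ebus$mdc, 60.0)
  expect_lt(ebus$p_value, 0.001)

  st3 <- row("Stage 3 receiving ST+RT")
  expect_equal(st3$traditional, 100 * 8 / 14, tolerance = 1e-9)

  # per-stage rows exclude undetermined-stage patients
  s1 <- row("Mean oncology visits, stage 1")
  expect_equal(s1$n_traditional + s1$n_mdc, 133)

  single <- default_calibrated_cohort()
  single <- single[single$arm == "mdc", ]
  expect_error(utilization_report(single), "both")
})

test_that("utilization report serializes to CSV and JSON", {
  rep <- utilization_report(default_calibrated_cohort())
  f <- withr::local_tempfile(fileext = ".csv")
  write_utilization_report(rep, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(rep))
  j <- withr::local_tempfile(fileext = ".json")
  write_utilization_report(rep, j)
  expect_equal(jsonlite::read_json(j, simplifyVector = TRUE)$label, rep$label)
})
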