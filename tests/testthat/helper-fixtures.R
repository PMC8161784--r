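# Shared fixtures: calibrated default cohort built once per test run.
default_calibrated_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_cohort(default_cohort_spec(),
                                                seed = 1L, calibrated = TRUE)
    memo
  }
})

# tiny two-arm cohort for schema-level tests
tiny_cohort <- function() {
  spec <- cohort_spec(
    n = c(traditional = 6, mdc = 8),
    stage_props = list(
      traditional = c(`1` = 2, `2` = 1, `3` = 1, `4` = 1, undetermined = 1) / 6,
      mdc = c(`1` = 3, `2` = 2, `3` = 1, `4` = 1, undetermined = 1) / 8
    )
  )
  generate_cohort(spec, seed = 7, calibrated = TRUE)
}

# permutation oracle for the 2x2 chi-squared test: conditions on both table
# margins (hypergeometric draws of cell a) and compares the chi-squared
# statistic of each permuted table with the observed one. Ties with the
# observed statistic get half weight (mid-p), the standard convention when
# benchmarking a continuous asymptotic p against a discrete permutation null.
permutation_prop_p <- function(x_a, n_a, x_b, n_b, B = 10000, seed = 99) {
  chisq_stat <- function(a) {
    tab <- cbind(c(a, n_a - a), c(x_a + x_b - a, n_b - (x_a + x_b - a)))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  obs <- chisq_stat(x_a)
  with_seed(seed, {
    draws <- stats::rhyper(B, m = n_a, n = n_b, k = x_a + x_b)
    stat <- vapply(draws, chisq_stat, numeric(1))
    mean(stat > obs + 1e-12) + 0.5 * mean(abs(stat - obs) <= 1e-12)
  })
}
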