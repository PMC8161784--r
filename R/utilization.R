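## Resource-utilization comparisons between the traditional and MDC arms:
## per-stage mean oncology visits, biopsies and staging imaging per patient,
## EBUS-TBNA uptake among stage-2/3 patients, and treatment-receipt
## proportions, with two-sample significance tests.

#' Mean utilization of a resource in one arm
#'
#' Arithmetic mean of a count field over qualifying patients. When a stage
#' filter is given, undetermined-stage patients are excluded (they are not
#' part of per-stage subgroup analyses); without a filter all patients in the
#' arm contribute.
#'
#' @param cohort an `mdc_cohort` data.frame.
#' @param arm `"traditional"` or `"mdc"`.
#' @param field one of `"oncology_visits"`, `"biopsies"`, `"staging_imaging"`.
#' @param stage optional stage filter, a subset of `c("1","2","3","4")`.
#' @return list with `mean` and `n`.
#' @export
mean_utilization <- function(cohort, arm,
                             field = c("oncology_visits", "biopsies",
                                       "staging_imaging"),
                             stage = NULL) {
  field <- match.arg(field)
  check_cohort(cohort)
  d <- cohort[cohort$arm == arm, ]
  if (!is.null(stage)) {
    if (any(stage == "undetermined"))
      fail_field("stage", "undetermined-stage patients have no subgroup")
    d <- d[d$stage %in% stage, ]
  }
  if (nrow(d) == 0)
    stop(sprintf("no %s patients in stratum", arm), call. = FALSE)
  list(mean = mean(d[[field]]), n = nrow(d))
}

new_comparison <- function(groups, values, method, statistic, df, p_value, n,
                           kind = c("means", "proportions")) {
  structure(list(
    groups = groups, values = values, difference = unname(values[1] - values[2]),
    method = method, statistic = unname(statistic),
    df = if (is.null(df)) NA_real_ else unname(df),
    p_value = unname(p_value), n = n, kind = match.arg(kind)
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  unit <- if (x$kind == "proportions") "%" else ""
  cat(sprintf("%s: %s %.3g%s vs %s %.3g%s (diff %.3g), %s: stat = %.4g, p = %.4g\n",
              x$kind, x$groups[1], x$values[1], unit, x$groups[2], x$values[2],
              unit, x$difference, x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Two-sample comparison of means
#'
#' Unpaired two-sided t-test; Welch (unequal variances) by default, with the
#' classical equal-variance test available.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param method `"welch_t"` (default) or `"student_t"`.
#' @param labels length-2 character vector naming the groups.
#' @return a `comparison_result` (difference is `mean(a) - mean(b)`).
#' @export
compare_means <- function(a, b, method = c("welch_t", "student_t"),
                          labels = c("a", "b")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = (method == "student_t"))
  new_comparison(labels, stats::setNames(c(mean(a), mean(b)), labels),
                 method, tt$statistic, tt$parameter, tt$p.value,
                 c(length(a), length(b)), "means")
}

#' Two-sample comparison of proportions
#'
#' Compares successes/n between two groups. The default chi-squared test is
#' computed without continuity correction; with `method = "auto"` Fisher's
#' exact test is substituted whenever any expected cell count is below 5.
#' Proportions are reported as percentages.
#'
#' @param x_a,n_a successes and trials in the first group.
#' @param x_b,n_b successes and trials in the second group.
#' @param method `"auto"`, `"chi_squared"`, or `"fisher_exact"`.
#' @param correct apply Yates continuity correction to the chi-squared test.
#' @param labels group names.
#' @return a `comparison_result`; `values` are percentages, `counts` kept in
#'   `n` as trials and in `successes`.
#' @export
compare_proportions <- function(x_a, n_a, x_b, n_b,
                                method = c("auto", "chi_squared",
                                           "fisher_exact"),
                                correct = FALSE, labels = c("a", "b")) {
  method <- match.arg(method)
  for (v in list(c(x_a, n_a), c(x_b, n_b))) {
    if (v[2] < 1) fail_field("n", "each group needs at least one trial")
    if (v[1] < 0 || v[1] > v[2])
      fail_field("successes", "must satisfy 0 <= successes <= n")
  }
  tab <- matrix(c(x_a, n_a - x_a, x_b, n_b - x_b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher_exact" else "chi_squared"
  if (method == "chi_squared") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    stat <- ht$statistic; df <- ht$parameter
  } else {
    ht <- stats::fisher.test(tab)
    stat <- ht$estimate; df <- NULL
  }
  vals <- stats::setNames(100 * c(x_a / n_a, x_b / n_b), labels)
  res <- new_comparison(labels, vals, method, stat, df, ht$p.value,
                        c(n_a, n_b), "proportions")
  res$successes <- c(x_a, x_b)
  res
}

#' One-way comparison of k group means
#'
#' Generic one-way ANOVA (Welch's variant optional) across two or more
#' groups, exposed for multi-group utilization contrasts.
#'
#' @param groups named list of numeric vectors.
#' @param var_equal assume equal variances (classical one-way ANOVA).
#' @return list with `statistic` (F), `df`, `p_value`, and group means.
#' @export
compare_anova <- function(groups, var_equal = TRUE) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(y ~ g, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       means = vapply(groups, mean, numeric(1)))
}

#' Full utilization comparison table
#'
#' Builds the arm-versus-arm resource-utilization report: mean oncology
#' visits for all patients and per stage, mean biopsies and staging imaging
#' per patient, EBUS-TBNA uptake among stage-2/3 patients, and per-stage
#' treatment-receipt proportions. Undetermined-stage patients are excluded
#' from per-stage visit and treatment rows (but contribute to the
#' all-patient means).
#'
#' @param cohort an `mdc_cohort` containing both arms.
#' @param mean_test,prop_test test choices forwarded to [compare_means()] /
#'   [compare_proportions()].
#' @return a `utilization_report`: data.frame with one row per comparison
#'   (label, per-arm value, n, test, statistic, p-value).
#' @export
utilization_report <- function(cohort, mean_test = "welch_t",
                               prop_test = "auto") {
  check_cohort(cohort)
  if (!all(ARMS %in% cohort$arm))
    stop("cohort must contain both a traditional and an mdc arm",
         call. = FALSE)
  tr <- cohort[cohort$arm == "traditional", ]
  md <- cohort[cohort$arm == "mdc", ]
  rows <- list()
  add_mean_row <- function(label, a, b) {
    cmp <- compare_means(a, b, mean_test, labels = ARMS)
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, type = "mean", traditional = mean(a), mdc = mean(b),
      n_traditional = length(a), n_mdc = length(b), test = cmp$method,
      statistic = cmp$statistic, p_value = cmp$p_value,
      stringsAsFactors = FALSE)
  }
  add_prop_row <- function(label, xa, na, xb, nb) {
    cmp <- compare_proportions(xa, na, xb, nb, prop_test, labels = ARMS)
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, type = "proportion",
      traditional = 100 * xa / na, mdc = 100 * xb / nb,
      n_traditional = na, n_mdc = nb, test = cmp$method,
      statistic = cmp$statistic, p_value = cmp$p_value,
      stringsAsFactors = FALSE)
  }

  add_mean_row("Mean oncology visits, all patients",
               tr$oncology_visits, md$oncology_visits)
  for (s in c("1", "2", "3", "4"))
    add_mean_row(sprintf("Mean oncology visits, stage %s", s),
                 tr$oncology_visits[tr$stage == s],
                 md$oncology_visits[md$stage == s])
  add_mean_row("Mean biopsies per patient", tr$biopsies, md$biopsies)
  add_mean_row("Mean staging imaging per patient",
               tr$staging_imaging, md$staging_imaging)

  tr_el <- tr$stage %in% c("2", "3"); md_el <- md$stage %in% c("2", "3")
  add_prop_row("EBUS-TBNA for stage 2/3 patients",
               sum(tr$ebus_performed[tr_el]), sum(tr_el),
               sum(md$ebus_performed[md_el]), sum(md_el))

  has_tok <- function(d, tok) {
    vapply(strsplit(d$treatments, ";", fixed = TRUE),
           function(t) all(strsplit(tok, ";", fixed = TRUE)[[1]] %in% t),
           logical(1))
  }
  trt <- default_treatment_rates()[, c("stage", "treatment")]
  for (r in seq_len(nrow(trt))) {
    s <- trt$stage[r]; tok <- trt$treatment[r]
    a <- tr[tr$stage == s, ]; b <- md[md$stage == s, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    add_prop_row(sprintf("Stage %s receiving %s", s, gsub(";", "+", tok)),
                 sum(has_tok(a, tok)), nrow(a), sum(has_tok(b, tok)), nrow(b))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("utilization_report", "data.frame")
  out
}

#' Serialize a utilization report
#'
#' @param report a `utilization_report`.
#' @param path output file; `.csv` or `.json` by extension.
#' @return `path`, invisibly.
#' @export
write_utilization_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else stop("unsupported output format: ", ext, call. = FALSE)
  invisible(path)
}
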