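## Economic analysis of invasive mediastinal staging by EBUS-TBNA for
## stage-2/3 lung cancer: per-arm pathway costs (procedure, out-of-pocket,
## productivity), QALYs gained, the incremental cost-effectiveness ratio
## (ICER), and the willingness-to-pay threshold quantities.

ebus_parameter_fields <- c(
  "arm", "n_procedures", "n_eligible", "procedure_cost",
  "parking_cost_per_visit", "prop_requiring_parking", "travel_cost_per_visit",
  "hours_forgone", "prop_under65", "caregivers_per_procedure",
  "caregiver_employment_prop", "wage_per_hour", "qaly_per_procedure"
)

#' Per-arm inputs of the EBUS-TBNA staging pathway
#'
#' Defaults are the published unit variables: CAD 1577 per procedure
#' (conscious sedation), CAD 9.00 parking with 50% of patients requiring
#' parking, CAD 59.14 return travel, 7.5 h forgone (travel, parking,
#' procedure, recovery) at CAD 29.55/h, one caregiver per procedure with 50%
#' employed, and 0.071 QALY attributed per procedure. An alternative
#' published QALY weight of 0.015 exists but is not the default.
#'
#' @param arm arm label (`"traditional"` or `"mdc"`).
#' @param n_procedures EBUS-TBNA procedures performed.
#' @param n_eligible stage-2/3 patients eligible for staging
#'   (`n_procedures <= n_eligible`).
#' @param procedure_cost CAD per procedure.
#' @param parking_cost_per_visit CAD per procedure visit.
#' @param prop_requiring_parking fraction of patients who park.
#' @param travel_cost_per_visit CAD per procedure visit.
#' @param hours_forgone hours off work per procedure.
#' @param prop_under65 working-age fraction of staged patients (applied as a
#'   fraction of procedures, unrounded).
#' @param caregivers_per_procedure caregivers accompanying each procedure.
#' @param caregiver_employment_prop employed fraction of caregivers.
#' @param wage_per_hour CAD per hour.
#' @param qaly_per_procedure QALY gained per procedure.
#' @return an object of class `ebus_arm_parameters`.
#' @export
ebus_arm_parameters <- function(arm, n_procedures, n_eligible,
                                procedure_cost = 1577,
                                parking_cost_per_visit = 9.00,
                                prop_requiring_parking = 0.50,
                                travel_cost_per_visit = 59.14,
                                hours_forgone = 7.5,
                                prop_under65 = 1 / 3,
                                caregivers_per_procedure = 1,
                                caregiver_employment_prop = 0.50,
                                wage_per_hour = 29.55,
                                qaly_per_procedure = 0.071) {
  n_procedures <- check_count(n_procedures, "n_procedures")
  n_eligible <- check_count(n_eligible, "n_eligible")
  if (n_procedures > n_eligible)
    fail_field("n_procedures", "cannot exceed n_eligible")
  p <- list(
    arm = arm, n_procedures = n_procedures, n_eligible = n_eligible,
    procedure_cost = check_nonneg(procedure_cost, "procedure_cost"),
    parking_cost_per_visit = check_nonneg(parking_cost_per_visit,
                                          "parking_cost_per_visit"),
    prop_requiring_parking = check_prob(prop_requiring_parking,
                                        "prop_requiring_parking"),
    travel_cost_per_visit = check_nonneg(travel_cost_per_visit,
                                         "travel_cost_per_visit"),
    hours_forgone = check_nonneg(hours_forgone, "hours_forgone"),
    prop_under65 = check_prob(prop_under65, "prop_under65"),
    caregivers_per_procedure = check_nonneg(caregivers_per_procedure,
                                            "caregivers_per_procedure"),
    caregiver_employment_prop = check_prob(caregiver_employment_prop,
                                           "caregiver_employment_prop"),
    wage_per_hour = check_nonneg(wage_per_hour, "wage_per_hour"),
    qaly_per_procedure = check_nonneg(qaly_per_procedure,
                                      "qaly_per_procedure")
  )
  class(p) <- "ebus_arm_parameters"
  p
}

#' Published per-arm EBUS parameter sets
#'
#' Traditional arm: 3 procedures among 20 eligible stage-2/3 patients, 1/3
#' of staged patients under 65. MDC arm: 57 procedures among 95 eligible,
#' 19/57 under 65.
#'
#' @param ... overrides forwarded to [ebus_arm_parameters()].
#' @return an `ebus_arm_parameters` object.
#' @export
ebus_traditional_defaults <- function(...) {
  args <- utils::modifyList(
    list(arm = "traditional", n_procedures = 3, n_eligible = 20,
         prop_under65 = 1 / 3), list(...))
  do.call(ebus_arm_parameters, args)
}

#' @rdname ebus_traditional_defaults
#' @export
ebus_mdc_defaults <- function(...) {
  args <- utils::modifyList(
    list(arm = "mdc", n_procedures = 57, n_eligible = 95,
         prop_under65 = 19 / 57), list(...))
  do.call(ebus_arm_parameters, args)
}

#' Read EBUS arm parameters from YAML or JSON
#'
#' @param path config file path holding one arm's fields.
#' @return an `ebus_arm_parameters` object.
#' @export
read_ebus_parameters <- function(path) {
  raw <- read_config_file(path)
  unknown <- setdiff(names(raw), ebus_parameter_fields)
  if (length(unknown)) fail_field(unknown[1], "not an EBUS arm parameter")
  do.call(ebus_arm_parameters, raw)
}

#' Per-arm EBUS pathway costs
#'
#' @param p an [ebus_arm_parameters()] object.
#' @return list of unrounded components (`procedural`, `parking`, `travel`,
#'   `out_of_pocket`, `patient_productivity`, `caregiver_productivity`,
#'   `productivity`, `total`) and whole-dollar display fields (`*_cad`);
#'   `out_of_pocket_cad` rounds the exact subtotal, `productivity_cad` and
#'   `total_cad` sum rounded components, matching the published table
#'   arithmetic.
#' @export
arm_costs <- function(p) {
  stopifnot(inherits(p, "ebus_arm_parameters"))
  n <- p$n_procedures
  procedural <- n * p$procedure_cost
  parking <- n * p$parking_cost_per_visit * p$prop_requiring_parking
  travel <- n * p$travel_cost_per_visit
  oop <- parking + travel
  patient <- n * p$prop_under65 * p$hours_forgone * p$wage_per_hour
  caregiver <- n * p$caregivers_per_procedure * p$caregiver_employment_prop *
    p$hours_forgone * p$wage_per_hour
  prod <- patient + caregiver
  list(
    procedural = procedural, parking = parking, travel = travel,
    out_of_pocket = oop, patient_productivity = patient,
    caregiver_productivity = caregiver, productivity = prod,
    total = procedural + oop + prod,
    procedural_cad = round_cad(procedural),
    parking_cad = round_cad(parking), travel_cad = round_cad(travel),
    out_of_pocket_cad = round_cad(oop),
    patient_productivity_cad = round_cad(patient),
    caregiver_productivity_cad = round_cad(caregiver),
    productivity_cad = round_cad(patient) + round_cad(caregiver),
    total_cad = round_cad(procedural) + round_cad(oop) +
      round_cad(patient) + round_cad(caregiver)
  )
}

#' Per-arm QALYs from EBUS-TBNA staging
#'
#' @param p an [ebus_arm_parameters()] object.
#' @return list with `qalys` (unrounded, procedures x QALY/procedure) and
#'   `qalys_display` (rounded to 2 decimals).
#' @export
arm_qalys <- function(p) {
  stopifnot(inherits(p, "ebus_arm_parameters"))
  q <- p$n_procedures * p$qaly_per_procedure
  list(qalys = q, qalys_display = round_half_away(q, 2))
}

#' Incremental cost-effectiveness of EBUS-TBNA staging, MDC vs traditional
#'
#' Computes per-arm costs and QALYs, the incremental cost and QALYs (from
#' unrounded arm totals), the ICER (incremental cost per QALY), and the QALY
#' difference needed to meet a willingness-to-pay threshold
#' (incremental cost / WTP). The displayed QALY difference follows the
#' published presentation: per-arm QALYs rounded to 2 decimals before
#' subtracting. If the incremental QALYs are zero the ICER is flagged
#' undefined rather than reported as a number.
#'
#' @param traditional,mdc [ebus_arm_parameters()] for the two arms.
#' @param wtp willingness-to-pay threshold, CAD/QALY (> 0).
#' @return an object of class `ebus_result`.
#' @examples
#' res <- ebus_icer(ebus_traditional_defaults(), ebus_mdc_defaults())
#' res$cost_per_qaly
#' @export
ebus_icer <- function(traditional, mdc, wtp = 80000) {
  stopifnot(inherits(traditional, "ebus_arm_parameters"),
            inherits(mdc, "ebus_arm_parameters"))
  if (!is.numeric(wtp) || wtp <= 0)
    fail_field("wtp", "must be a positive CAD/QALY threshold")
  ct <- arm_costs(traditional); cm <- arm_costs(mdc)
  qt <- arm_qalys(traditional); qm <- arm_qalys(mdc)
  inc_cost <- cm$total - ct$total
  inc_qaly <- qm$qalys - qt$qalys
  undefined <- inc_qaly == 0
  icer <- if (undefined) NA_real_ else inc_cost / inc_qaly
  res <- structure(list(
    arms = list(traditional = list(params = traditional, costs = ct,
                                   qalys = qt),
                mdc = list(params = mdc, costs = cm, qalys = qm)),
    incremental_cost = inc_cost,
    incremental_qalys = inc_qaly,
    incremental_qalys_display = qm$qalys_display - qt$qalys_display,
    cost_per_qaly = icer,
    icer_undefined = undefined,
    wtp_threshold = wtp,
    qalys_needed_at_wtp = inc_cost / wtp,
    cost_effective = !undefined && inc_qaly > 0 && icer <= wtp
  ), class = "ebus_result")
  res
}

#' Cost-effectiveness verdict with narrative
#'
#' @param result an [ebus_icer()] `ebus_result`.
#' @return list with `cost_effective` (TRUE iff the ICER is defined, the MDC
#'   arm adds QALYs, and the ICER is at or below the threshold),
#'   `observed_qaly_difference`, `needed_qaly_difference`, and a `narrative`
#'   string.
#' @export
cost_effectiveness_verdict <- function(result) {
  stopifnot(inherits(result, "ebus_result"))
  if (result$icer_undefined) {
    return(list(cost_effective = FALSE,
                observed_qaly_difference = 0,
                needed_qaly_difference = result$qalys_needed_at_wtp,
                narrative = "ICER undefined: the two arms gain identical QALYs, so no cost-per-QALY can be computed."))
  }
  obs <- result$incremental_qalys
  need <- result$qalys_needed_at_wtp
  ok <- result$cost_effective
  narrative <- sprintf(
    "Incremental cost CAD %.0f for %.3f QALYs gained: CAD %.0f per QALY %s the CAD %.0f/QALY willingness-to-pay threshold (QALY difference needed at threshold: %.2f; observed: %.2f).",
    result$incremental_cost, obs, result$cost_per_qaly,
    if (ok) "falls below" else "exceeds", result$wtp_threshold,
    round_half_away(need, 2), result$incremental_qalys_display)
  list(cost_effective = ok, observed_qaly_difference = obs,
       needed_qaly_difference = need, narrative = narrative)
}

#' @export
print.ebus_result <- function(x, ...) {
  fmt <- function(v) formatC(round_cad(v), format = "d", big.mark = ",")
  cat("EBUS-TBNA invasive mediastinal staging: threshold analysis (2019 CAD)\n")
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("  %-12s %2d procedures / %2d eligible: total $%s (procedure $%s, out-of-pocket $%s, productivity $%s), QALYs %.2f\n",
                arm, a$params$n_procedures, a$params$n_eligible,
                fmt(a$costs$total_cad), fmt(a$costs$procedural_cad),
                fmt(a$costs$out_of_pocket_cad), fmt(a$costs$productivity_cad),
                a$qalys$qalys_display))
  }
  if (x$icer_undefined) {
    cat("  ICER undefined (zero incremental QALYs)\n")
  } else {
    cat(sprintf("  Incremental: $%s for %.2f QALYs -> $%s/QALY (WTP $%s/QALY; needed %.2f QALYs)\n",
                fmt(x$incremental_cost), x$incremental_qalys_display,
                fmt(x$cost_per_qaly), fmt(x$wtp_threshold),
                round_half_away(x$qalys_needed_at_wtp, 2)))
    cat(sprintf("  Cost-effective at threshold: %s\n", x$cost_effective))
  }
  invisible(x)
}

#' @export
as.data.frame.ebus_result <- function(x, ...) {
  g <- function(arm, f) x$arms[[arm]]$costs[[f]]
  data.frame(
    item = c("EBUS-TBNA procedures", "Quality-adjusted life years",
             "Procedural costs", "Parking cost", "Return travel cost",
             "Total out-of-pocket costs", "Patient opportunity cost",
             "Caregiver opportunity cost", "Total productivity loss costs",
             "Total EBUS-TBNA cost"),
    traditional = c(x$arms$traditional$params$n_procedures,
                    x$arms$traditional$qalys$qalys_display,
                    g("traditional", "procedural_cad"),
                    g("traditional", "parking_cad"),
                    g("traditional", "travel_cad"),
                    g("traditional", "out_of_pocket_cad"),
                    g("traditional", "patient_productivity_cad"),
                    g("traditional", "caregiver_productivity_cad"),
                    g("traditional", "productivity_cad"),
                    g("traditional", "total_cad")),
    mdc = c(x$arms$mdc$params$n_procedures, x$arms$mdc$qalys$qalys_display,
            g("mdc", "procedural_cad"), g("mdc", "parking_cad"),
            g("mdc", "travel_cad"), g("mdc", "out_of_pocket_cad"),
            g("mdc", "patient_productivity_cad"),
            g("mdc", "caregiver_productivity_cad"),
            g("mdc", "productivity_cad"), g("mdc", "total_cad")),
    stringsAsFactors = FALSE
  )
}

#' Serialize an EBUS result
#'
#' @param x an `ebus_result`.
#' @param path output file; table-shaped CSV or JSON by extension.
#' @return `path`, invisibly.
#' @export
write_ebus_result <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (ext == "json") {
    out <- list(
      table = as.data.frame(x),
      incremental_cost = x$incremental_cost,
      incremental_qalys = x$incremental_qalys,
      incremental_qalys_display = x$incremental_qalys_display,
      cost_per_qaly = x$cost_per_qaly,
      wtp_threshold = x$wtp_threshold,
      qalys_needed_at_wtp = x$qalys_needed_at_wtp,
      cost_effective = x$cost_effective
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported output format: ", ext, call. = FALSE)
  invisible(path)
}
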