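## Societal-perspective base-case cost-savings model.
##
## The MDC consolidates oncology consultations, saving an average number of
## visits per patient. Each avoided visit saves: out-of-pocket costs (parking
## and return travel), productivity losses valued by the human-capital
## approach (hours away from work times the average wage, counted for
## working-age patients and for the employed fraction of accompanying
## caregivers), and administrative booking time. Intermediate quantities are
## carried unrounded; displayed dollar amounts follow the conventions of the
## published tables (see the methods vignette): line items and the
## productivity subtotal round each component to the nearest dollar (halves
## away from zero), the out-of-pocket subtotal rounds the exact sum, and the
## grand total sums the three subtotals.

cost_parameter_fields <- c(
  "visits_saved_per_patient", "n_patients", "caregivers_per_visit",
  "prop_under65", "parking_cost_per_visit", "travel_cost_per_visit",
  "return_distance_km", "travel_rate_per_km", "clinic_visit_hours",
  "time_forgone_hours", "wage_per_hour", "caregiver_employment_prop",
  "admin_cost_per_visit", "hours_off_work_override", "override_applies_to"
)

#' Unit variables of the visit-savings cost model
#'
#' Defaults are the published base case: 1.06 visits saved per MDC patient
#' over 350 patients, 1.25 caregivers per visit, 23% of patients under 65
#' (working age), CAD 6.00 parking and CAD 59.14 return travel per visit,
#' 1.26 h clinic visit plus 1.27 h forgone (travel, parking, wayfinding),
#' CAD 29.55/h wage, 50% of caregivers employed, and CAD 1.37 administrative
#' booking cost per visit. All amounts are 2019 CAD.
#'
#' Travel may alternatively be specified in distance mode by giving both
#' `return_distance_km` and `travel_rate_per_km` (e.g. 102 km at CAD
#' 0.58/km); this is mutually exclusive with an explicit
#' `travel_cost_per_visit`.
#'
#' `hours_off_work_override`, when set, replaces the clinic + forgone time
#' with a flat number of hours off work for the parties named by
#' `override_applies_to` (`"patients"`, `"caregivers"`, or `"both"`) — the
#' convention used by the worst-case sensitivity scenario (7.5 h, a full
#' working day).
#'
#' @param visits_saved_per_patient mean oncology visits saved per patient.
#' @param n_patients MDC cohort size.
#' @param caregivers_per_visit mean caregivers accompanying each visit.
#' @param prop_under65 working-age (under-65) fraction of patients.
#' @param parking_cost_per_visit CAD per visit.
#' @param travel_cost_per_visit CAD per visit (cost mode); `NULL` in
#'   distance mode.
#' @param return_distance_km,travel_rate_per_km distance-mode travel inputs.
#' @param clinic_visit_hours,time_forgone_hours visit time components, hours.
#' @param wage_per_hour CAD per hour (human-capital valuation).
#' @param caregiver_employment_prop fraction of caregivers incurring
#'   productivity loss.
#' @param admin_cost_per_visit CAD of administrative booking time per visit.
#' @param hours_off_work_override optional flat hours off work.
#' @param override_applies_to who the override applies to.
#' @return an object of class `cost_parameters`.
#' @examples
#' p <- cost_parameters()
#' total_savings(p)
#' @export
cost_parameters <- function(visits_saved_per_patient = 1.06,
                            n_patients = 350,
                            caregivers_per_visit = 1.25,
                            prop_under65 = 0.23,
                            parking_cost_per_visit = 6.00,
                            travel_cost_per_visit = 59.14,
                            return_distance_km = NULL,
                            travel_rate_per_km = NULL,
                            clinic_visit_hours = 1.26,
                            time_forgone_hours = 1.27,
                            wage_per_hour = 29.55,
                            caregiver_employment_prop = 0.50,
                            admin_cost_per_visit = 1.37,
                            hours_off_work_override = NULL,
                            override_applies_to = c("both", "patients",
                                                    "caregivers")) {
  distance_mode <- !is.null(return_distance_km) || !is.null(travel_rate_per_km)
  if (distance_mode) {
    if (is.null(return_distance_km) || is.null(travel_rate_per_km))
      fail_field("return_distance_km",
                 "distance mode needs both return_distance_km and travel_rate_per_km")
    if (!missing(travel_cost_per_visit) && !is.null(travel_cost_per_visit))
      fail_field("travel_cost_per_visit",
                 "give either travel_cost_per_visit or the distance/rate pair, not both")
    check_nonneg(return_distance_km, "return_distance_km")
    check_nonneg(travel_rate_per_km, "travel_rate_per_km")
    travel_cost_per_visit <- return_distance_km * travel_rate_per_km
  }
  p <- list(
    visits_saved_per_patient = check_nonneg(visits_saved_per_patient,
                                            "visits_saved_per_patient"),
    n_patients = check_count(n_patients, "n_patients", positive = TRUE),
    caregivers_per_visit = check_nonneg(caregivers_per_visit,
                                        "caregivers_per_visit"),
    prop_under65 = check_prob(prop_under65, "prop_under65"),
    parking_cost_per_visit = check_nonneg(parking_cost_per_visit,
                                          "parking_cost_per_visit"),
    travel_cost_per_visit = check_nonneg(travel_cost_per_visit,
                                         "travel_cost_per_visit"),
    return_distance_km = return_distance_km,
    travel_rate_per_km = travel_rate_per_km,
    clinic_visit_hours = check_nonneg(clinic_visit_hours,
                                      "clinic_visit_hours"),
    time_forgone_hours = check_nonneg(time_forgone_hours,
                                      "time_forgone_hours"),
    wage_per_hour = check_nonneg(wage_per_hour, "wage_per_hour"),
    caregiver_employment_prop = check_prob(caregiver_employment_prop,
                                           "caregiver_employment_prop"),
    admin_cost_per_visit = check_nonneg(admin_cost_per_visit,
                                        "admin_cost_per_visit"),
    hours_off_work_override = if (!is.null(hours_off_work_override))
      check_nonneg(hours_off_work_override, "hours_off_work_override"),
    override_applies_to = match.arg(override_applies_to),
    travel_mode = if (distance_mode) "distance" else "cost"
  )
  class(p) <- "cost_parameters"
  p
}

#' Read cost parameters from YAML or JSON
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a validated [cost_parameters()] object.
#' @export
read_cost_parameters <- function(path) {
  raw <- read_config_file(path)
  unknown <- setdiff(names(raw), cost_parameter_fields)
  if (length(unknown))
    fail_field(unknown[1], "not a cost-model parameter")
  do.call(cost_parameters, raw)
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("Visit-savings cost model parameters (2019 CAD)\n")
  cat(sprintf("  %.2f visits saved/patient x %d patients; %.2f caregivers/visit\n",
              x$visits_saved_per_patient, x$n_patients,
              x$caregivers_per_visit))
  cat(sprintf("  parking %.2f, travel %.2f per visit (%s mode); admin %.2f\n",
              x$parking_cost_per_visit, x$travel_cost_per_visit,
              x$travel_mode, x$admin_cost_per_visit))
  if (is.null(x$hours_off_work_override)) {
    cat(sprintf("  time/visit %.2f h clinic + %.2f h forgone; wage %.2f/h\n",
                x$clinic_visit_hours, x$time_forgone_hours, x$wage_per_hour))
  } else {
    cat(sprintf("  flat %.2f h off work (%s); wage %.2f/h\n",
                x$hours_off_work_override, x$override_applies_to,
                x$wage_per_hour))
  }
  cat(sprintf("  under-65 fraction %.2f; caregiver employment %.2f\n",
              x$prop_under65, x$caregiver_employment_prop))
  invisible(x)
}

## hours off work per avoided visit, per party
time_per_visit <- function(p, party = c("patients", "caregivers")) {
  party <- match.arg(party)
  base <- p$clinic_visit_hours + p$time_forgone_hours
  ov <- p$hours_off_work_override
  if (!is.null(ov) && p$override_applies_to %in% c(party, "both")) ov else base
}

#' Number of visits saved
#'
#' @param params a [cost_parameters()] object.
#' @return list with `unrounded` (visits/patient x patients) and `rounded`
#'   (nearest integer, halves away from zero); the rounded count is the unit
#'   count the dollar figures are built on.
#' @export
visits_saved <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  u <- params$visits_saved_per_patient * params$n_patients
  list(unrounded = u, rounded = round_half_away(u))
}

#' Out-of-pocket (parking + travel) savings
#'
#' @param params a [cost_parameters()] object.
#' @return list with unrounded `parking`, `travel`, `total`, and displayed
#'   (whole-dollar) `parking_cad`, `travel_cad`, `total_cad`,
#'   `per_patient_cad`.
#' @export
out_of_pocket_savings <- function(params) {
  v <- visits_saved(params)$rounded
  parking <- v * params$parking_cost_per_visit
  travel <- v * params$travel_cost_per_visit
  total <- parking + travel
  list(parking = parking, travel = travel, total = total,
       parking_cad = round_cad(parking), travel_cad = round_cad(travel),
       total_cad = round_cad(total),
       per_patient_cad = round_cad(total / params$n_patients))
}

#' Productivity-loss savings (human-capital approach)
#'
#' Patient component: rounded visits saved x under-65 fraction x hours per
#' visit x wage. Caregiver component: unrounded caregiver visits saved
#' (caregivers/visit x rounded visits saved) x employed fraction x hours x
#' wage. The caregiver visit count stays unrounded inside the formula (e.g.
#' 463.75, displayed as 464).
#'
#' @param params a [cost_parameters()] object.
#' @return list with unrounded `patient`, `caregiver`, `total`,
#'   `caregiver_visits`, and displayed `patient_cad`, `caregiver_cad`,
#'   `total_cad` (sum of the two rounded components).
#' @export
productivity_savings <- function(params) {
  v <- visits_saved(params)$rounded
  cg_visits <- params$caregivers_per_visit * v
  patient <- v * params$prop_under65 * time_per_visit(params, "patients") *
    params$wage_per_hour
  caregiver <- cg_visits * params$caregiver_employment_prop *
    time_per_visit(params, "caregivers") * params$wage_per_hour
  list(patient = patient, caregiver = caregiver, total = patient + caregiver,
       caregiver_visits = cg_visits,
       patient_cad = round_cad(patient), caregiver_cad = round_cad(caregiver),
       total_cad = round_cad(patient) + round_cad(caregiver))
}

#' Administrative (booking-time) savings
#'
#' @param params a [cost_parameters()] object.
#' @return list with unrounded `total` and displayed `total_cad`.
#' @export
admin_savings <- function(params) {
  v <- visits_saved(params)$rounded
  total <- v * params$admin_cost_per_visit
  list(total = total, total_cad = round_cad(total))
}

#' Assemble the full cost-savings breakdown
#'
#' Combines out-of-pocket, productivity and administrative savings into a
#' `cost_breakdown`. Unrounded components are preserved in `$unrounded`
#' (their grand total drives extrapolation); whole-dollar display fields sit
#' at the top level.
#'
#' @param params a [cost_parameters()] object.
#' @return an object of class `cost_breakdown`.
#' @examples
#' b <- total_savings(cost_parameters())
#' b$grand_total      # 48389
#' b$per_patient      # 138
#' @export
total_savings <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  v <- visits_saved(params)
  oop <- out_of_pocket_savings(params)
  prod <- productivity_savings(params)
  adm <- admin_savings(params)
  grand_u <- oop$total + prod$total + adm$total
  grand <- oop$total_cad + prod$total_cad + adm$total_cad
  structure(list(
    params = params,
    visits_saved = v$unrounded,
    visits_saved_rounded = v$rounded,
    caregiver_visits_saved = prod$caregiver_visits,
    parking_savings = oop$parking_cad,
    travel_savings = oop$travel_cad,
    out_of_pocket_total = oop$total_cad,
    out_of_pocket_per_patient = oop$per_patient_cad,
    patient_productivity_savings = prod$patient_cad,
    caregiver_productivity_savings = prod$caregiver_cad,
    productivity_total = prod$total_cad,
    admin_savings = adm$total_cad,
    grand_total = grand,
    per_patient = round_cad(grand / params$n_patients),
    unrounded = list(
      parking = oop$parking, travel = oop$travel,
      out_of_pocket = oop$total,
      patient_productivity = prod$patient,
      caregiver_productivity = prod$caregiver,
      productivity = prod$total,
      admin = adm$total,
      grand_total = grand_u
    )
  ), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "d", big.mark = ",")
  cat("Cost savings, MDC vs traditional model (2019 CAD)\n")
  cat(sprintf("  Visits saved: %d (%.2f/patient x %d patients); caregiver visits %.2f\n",
              x$visits_saved_rounded, x$params$visits_saved_per_patient,
              x$params$n_patients, x$caregiver_visits_saved))
  cat(sprintf("  Out-of-pocket:   parking $%s + travel $%s = $%s ($%s/patient)\n",
              fmt(x$parking_savings), fmt(x$travel_savings),
              fmt(x$out_of_pocket_total), fmt(x$out_of_pocket_per_patient)))
  cat(sprintf("  Productivity:    patient $%s + caregiver $%s = $%s\n",
              fmt(x$patient_productivity_savings),
              fmt(x$caregiver_productivity_savings), fmt(x$productivity_total)))
  cat(sprintf("  Administrative:  $%s\n", fmt(x$admin_savings)))
  cat(sprintf("  Total savings:   $%s ($%s/patient)\n",
              fmt(x$grand_total), fmt(x$per_patient)))
  invisible(x)
}

#' @export
as.data.frame.cost_breakdown <- function(x, ...) {
  data.frame(
    item = c("Patient visits saved", "Caregiver visits saved",
             "Parking cost savings", "Return travel cost savings",
             "Total out-of-pocket cost savings",
             "Out-of-pocket savings per patient",
             "Patient opportunity cost savings",
             "Caregiver opportunity cost savings",
             "Total productivity loss savings",
             "Administrative (booking) savings",
             "Total savings", "Total savings per patient"),
    value = c(x$visits_saved_rounded, round_cad(x$caregiver_visits_saved),
              x$parking_savings, x$travel_savings, x$out_of_pocket_total,
              x$out_of_pocket_per_patient, x$patient_productivity_savings,
              x$caregiver_productivity_savings, x$productivity_total,
              x$admin_savings, x$grand_total, x$per_patient),
    stringsAsFactors = FALSE
  )
}

#' Serialize a cost breakdown
#'
#' @param x a `cost_breakdown`.
#' @param path output file; two-column CSV or JSON by extension.
#' @return `path`, invisibly.
#' @export
write_cost_breakdown <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (ext == "json") {
    keep <- setdiff(names(x), "params")
    jsonlite::write_json(x[keep], path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported output format: ", ext, call. = FALSE)
  invisible(path)
}

#' Extrapolate savings to a larger cohort
#'
#' Scales the unrounded per-patient grand total to a target cohort size
#' (e.g. the program's projected three-year volume of 585 patients).
#'
#' @param breakdown a `cost_breakdown`.
#' @param target_n_patients projected number of patients (> 0 unless 0, which
#'   returns 0).
#' @return extrapolated total savings in CAD (unrounded).
#' @export
extrapolate_savings <- function(breakdown, target_n_patients) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  if (target_n_patients < 0)
    fail_field("target_n_patients", "must be non-negative")
  breakdown$unrounded$grand_total / breakdown$params$n_patients *
    target_n_patients
}
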