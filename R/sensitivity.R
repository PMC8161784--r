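## Deterministic sensitivity analysis over the cost model: named scenarios
## (joint parameter overrides, including the published best/worst cases) and
## one-way parameter sweeps.

#' Define a sensitivity scenario
#'
#' A scenario is a named set of overrides on [cost_parameters()] fields.
#' Override keys are validated against the parameter schema when the
#' scenario is evaluated.
#'
#' @param name scenario label.
#' @param ... overrides, e.g. `parking_cost_per_visit = 4.5`.
#' @param overrides alternatively, a named list of overrides.
#' @return an object of class `scenario`.
#' @export
scenario <- function(name, ..., overrides = NULL) {
  ov <- if (is.null(overrides)) list(...) else overrides
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == "")))
    fail_field("overrides", "every override must be named")
  structure(list(name = name, overrides = ov), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s':\n", x$name))
  if (!length(x$overrides)) cat("  (no overrides)\n")
  for (k in names(x$overrides))
    cat(sprintf("  %s = %s\n", k, format(x$overrides[[k]])))
  invisible(x)
}

#' Published best-case and worst-case scenarios
#'
#' Best case: 55.5-minute clinic visit (time forgone unchanged at 1.27 h),
#' CAD 4.50 parking, 25% of caregivers employed. Worst case: CAD 12 parking,
#' a flat 7.5 h off work for both patients and caregivers, 75% of caregivers
#' employed. Travel cost is held at base in both.
#'
#' @return a `scenario` object.
#' @export
best_case_scenario <- function() {
  scenario("best case",
           parking_cost_per_visit = 4.50,
           clinic_visit_hours = 55.5 / 60,
           caregiver_employment_prop = 0.25)
}

#' @rdname best_case_scenario
#' @export
worst_case_scenario <- function() {
  scenario("worst case",
           parking_cost_per_visit = 12,
           hours_off_work_override = 7.5,
           override_applies_to = "both",
           caregiver_employment_prop = 0.75)
}

## merge overrides into a cost_parameters object, revalidating via the
## constructor so scenario values obey the same invariants
apply_overrides <- function(base, overrides) {
  stopifnot(inherits(base, "cost_parameters"))
  unknown <- setdiff(names(overrides), cost_parameter_fields)
  if (length(unknown))
    fail_field(unknown[1], "not a cost-model parameter")
  args <- base[setdiff(cost_parameter_fields, "travel_cost_per_visit")]
  args <- args[!vapply(args, is.null, logical(1))]
  ## keep the base travel mode unless the scenario changes travel inputs
  if (base$travel_mode == "cost" ||
      any(c("travel_cost_per_visit") %in% names(overrides))) {
    args$travel_cost_per_visit <- base$travel_cost_per_visit
    args$return_distance_km <- NULL
    args$travel_rate_per_km <- NULL
  }
  for (k in names(overrides)) args[[k]] <- overrides[[k]]
  do.call(cost_parameters, args)
}

#' Evaluate a scenario against base parameters
#'
#' @param base a [cost_parameters()] object (unmodified by the call).
#' @param scen a [scenario()].
#' @return the [total_savings()] `cost_breakdown` under the merged
#'   parameters.
#' @export
evaluate_scenario <- function(base, scen) {
  stopifnot(inherits(scen, "scenario"))
  total_savings(apply_overrides(base, scen$overrides))
}

#' Multi-way (best/worst-case) sensitivity range
#'
#' @param base a [cost_parameters()] object.
#' @param scenarios list of [scenario()] objects (order preserved in the
#'   table). Defaults to the published best and worst cases.
#' @return list with `min`, `max` (grand totals, CAD) and `table`
#'   (data.frame of scenario name and grand total).
#' @export
multiway_range <- function(base, scenarios = list(best_case_scenario(),
                                                  worst_case_scenario())) {
  if (!length(scenarios))
    stop("need at least one scenario", call. = FALSE)
  totals <- vapply(scenarios,
                   function(s) evaluate_scenario(base, s)$grand_total,
                   numeric(1))
  tab <- data.frame(scenario = vapply(scenarios, `[[`, character(1), "name"),
                    grand_total = totals, stringsAsFactors = FALSE)
  list(min = min(totals), max = max(totals), table = tab)
}

#' One-way parameter sweep
#'
#' Evaluates the grand total across a grid of values for a single parameter,
#' all other fields at base — the input for a tornado-style display.
#'
#' @param base a [cost_parameters()] object.
#' @param field a [cost_parameters()] field name.
#' @param values numeric vector of values within the field's domain.
#' @return data.frame with columns `value` and `grand_total`.
#' @export
one_way_sweep <- function(base, field, values) {
  if (!field %in% cost_parameter_fields)
    fail_field(field, "not a cost-model parameter")
  if (!length(values)) fail_field("values", "must be non-empty")
  totals <- vapply(values, function(v) {
    ov <- stats::setNames(list(v), field)
    evaluate_scenario(base, scenario(paste0(field, "=", v), overrides = ov))$grand_total
  }, numeric(1))
  data.frame(value = values, grand_total = totals)
}

#' Read scenarios from a YAML or JSON list
#'
#' The file holds a list of `{name, overrides}` entries.
#'
#' @param path config file path.
#' @return list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  raw <- read_config_file(path)
  if (!is.null(raw$name)) raw <- list(raw)   # single scenario file
  lapply(raw, function(s) {
    if (is.null(s$name)) fail_field("name", "every scenario needs a name")
    scenario(s$name, overrides = as.list(s$overrides))
  })
}
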