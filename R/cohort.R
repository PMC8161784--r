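## Patient-level domain data and the synthetic cohort generator.
##
## A cohort is a plain data.frame (class "mdc_cohort") with one row per
## patient and a fixed column schema (see `cohort_columns`). Two arms are
## modelled: "traditional" (sequential referral) and "mdc" (multidisciplinary
## clinic). The generator has a calibrated mode, in which every marginal of
## the specification (stage counts, per-stage visit means, EBUS uptake,
## under-65 counts) is hit exactly up to integer rounding via deterministic
## largest-remainder allocation, and a sampled mode driven by a seed.

ARMS <- c("traditional", "mdc")
STAGES <- c("1", "2", "3", "4", "undetermined")
DIAGNOSES <- c("NSCLC", "SCLC", "presumed_LC", "non_LC")
TREATMENTS <- c("TS", "RT", "ST")

cohort_columns <- c(
  "patient_id", "arm", "diagnosis", "stage", "oncology_visits", "biopsies",
  "staging_imaging", "ebus_performed", "return_distance_km", "caregivers",
  "age_years", "treatments"
)

#' Specification of a two-arm synthetic lung-cancer cohort
#'
#' Collects every marginal the generator reproduces: per-arm sizes, stage and
#' diagnosis mixes, per-arm-per-stage mean oncology visits (diagnosis to first
#' treatment), mean biopsies and staging-imaging counts, EBUS-TBNA uptake
#' among stage-2/3 patients, return travel distance, caregiver distribution,
#' age structure and the under-65 (working-age) fraction, and per-stage
#' treatment-receipt rates.
#'
#' The defaults encode the published MDC evaluation cohort: 78 traditional
#' and 350 MDC patients, stage mix (e.g. 109/350 MDC stage 1), per-stage
#' visit means (e.g. stage-4: 2.55 traditional vs 1.29 MDC), EBUS uptake
#' 15% vs 60% of stage-2/3 patients, mean return distance 102 km, 1.25
#' caregivers per patient, and 23% of MDC patients under 65. Visit means for
#' the small undetermined-stage groups are not published; the defaults (3.6
#' traditional, 7/3 MDC) are calibrated so each arm's overall visit mean
#' equals the published all-patient mean (2.68 and 1.62).
#'
#' @param n named integer vector, patients per arm.
#' @param stage_props per-arm stage proportions over
#'   `c("1","2","3","4","undetermined")`, each summing to 1.
#' @param diagnosis_props per-arm diagnosis proportions over
#'   `c("NSCLC","SCLC","presumed_LC","non_LC")`.
#' @param visit_means per-arm named vector of mean oncology visits per stage.
#' @param visit_max truncation ceiling for sampled visit counts.
#' @param biopsy_mean,imaging_mean per-arm mean counts per patient.
#' @param distance_mean_km per-arm mean return (round-trip) distance, km.
#' @param distance_sdlog log-scale SD of the lognormal distance model.
#' @param caregiver_probs distribution of caregivers per patient over 1..4.
#' @param age_mean,age_sd per-arm age moments (years); ages are truncated to
#'   18-100.
#' @param ebus_prob per-arm probability that a stage-2/3 patient undergoes
#'   EBUS-TBNA invasive mediastinal staging.
#' @param under65_prop per-arm fraction of patients under 65.
#' @param treatment_rates data.frame with columns `stage`, `treatment`
#'   (semicolon-joined tokens from TS/RT/ST), and one rate column per arm.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [summarize_cohort()]
#' @export
cohort_spec <- function(
    n = c(traditional = 78, mdc = 350),
    stage_props = list(
      traditional = c(`1` = 24, `2` = 6, `3` = 14, `4` = 29,
                      undetermined = 5) / 78,
      mdc = c(`1` = 109, `2` = 26, `3` = 69, `4` = 143,
              undetermined = 3) / 350
    ),
    diagnosis_props = list(
      traditional = c(NSCLC = 69, SCLC = 9, presumed_LC = 0, non_LC = 0) / 78,
      mdc = c(NSCLC = 260, SCLC = 45, presumed_LC = 45, non_LC = 0) / 350
    ),
    visit_means = list(
      traditional = c(`1` = 2.29, `2` = 2.33, `3` = 3.43, `4` = 2.55,
                      undetermined = 3.6),
      mdc = c(`1` = 1.66, `2` = 2.13, `3` = 2.03, `4` = 1.29,
              undetermined = 7 / 3)
    ),
    visit_max = 8,
    biopsy_mean = c(traditional = 1.32, mdc = 1.17),
    imaging_mean = c(traditional = 2.24, mdc = 2.02),
    distance_mean_km = c(traditional = 102, mdc = 102),
    distance_sdlog = 0.6,
    caregiver_probs = c(`1` = 0.80, `2` = 0.16, `3` = 0.03, `4` = 0.01),
    age_mean = c(traditional = 70.0, mdc = 71.7),
    age_sd = c(traditional = 9.7, mdc = 9.1),
    ebus_prob = c(traditional = 0.15, mdc = 0.60),
    under65_prop = c(traditional = 0.23, mdc = 79 / 350),
    treatment_rates = default_treatment_rates()) {
  spec <- list(
    n = n, stage_props = stage_props, diagnosis_props = diagnosis_props,
    visit_means = visit_means, visit_max = visit_max,
    biopsy_mean = biopsy_mean, imaging_mean = imaging_mean,
    distance_mean_km = distance_mean_km, distance_sdlog = distance_sdlog,
    caregiver_probs = caregiver_probs, age_mean = age_mean, age_sd = age_sd,
    ebus_prob = ebus_prob, under65_prop = under65_prop,
    treatment_rates = treatment_rates
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @export
default_cohort_spec <- function() cohort_spec()

## Table-2 treatment receipt rows: rate = receiving patients / stage size
default_treatment_rates <- function() {
  data.frame(
    stage = c("1", "1", "2", "2", "3", "4"),
    treatment = c("TS", "RT", "TS", "RT", "ST;RT", "ST"),
    traditional = c(5 / 24, 21 / 24, 2 / 6, 5 / 6, 8 / 14, 11 / 29),
    mdc = c(15 / 109, 84 / 109, 6 / 26, 17 / 26, 37 / 69, 57 / 143),
    stringsAsFactors = FALSE
  )
}

validate_cohort_spec <- function(spec) {
  for (arm in ARMS) {
    if (is.na(spec$n[arm]) || spec$n[arm] < 1 || spec$n[arm] %% 1 != 0)
      fail_field(paste0("n[", arm, "]"), "must be a positive integer")
    check_simplex(spec$stage_props[[arm]], paste0("stage_props$", arm))
    check_simplex(spec$diagnosis_props[[arm]], paste0("diagnosis_props$", arm))
    if (length(spec$stage_props[[arm]]) != length(STAGES))
      fail_field(paste0("stage_props$", arm), "needs one proportion per stage")
    if (any(spec$visit_means[[arm]] < 0))
      fail_field(paste0("visit_means$", arm), "means must be non-negative")
    check_prob(spec$ebus_prob[[arm]], paste0("ebus_prob[", arm, "]"))
    check_prob(spec$under65_prop[[arm]], paste0("under65_prop[", arm, "]"))
    check_nonneg(spec$biopsy_mean[[arm]], paste0("biopsy_mean[", arm, "]"))
    check_nonneg(spec$imaging_mean[[arm]], paste0("imaging_mean[", arm, "]"))
    check_nonneg(spec$distance_mean_km[[arm]],
                 paste0("distance_mean_km[", arm, "]"))
  }
  check_simplex(spec$caregiver_probs, "caregiver_probs")
  if (length(spec$caregiver_probs) != 4)
    fail_field("caregiver_probs", "needs probabilities for 1..4 caregivers")
  rates <- unlist(spec$treatment_rates[ARMS])
  if (any(rates < 0 | rates > 1))
    fail_field("treatment_rates", "rates must lie in [0, 1]")
  spec
}

#' Read a cohort specification from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return a validated [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  raw <- read_config_file(path)
  if (!is.null(raw$treatment_rates))
    raw$treatment_rates <- as.data.frame(raw$treatment_rates,
                                         stringsAsFactors = FALSE)
  for (f in c("n", "biopsy_mean", "imaging_mean", "distance_mean_km",
              "age_mean", "age_sd", "ebus_prob", "under65_prop"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  for (f in c("stage_props", "diagnosis_props", "visit_means"))
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  if (!is.null(raw$caregiver_probs)) raw$caregiver_probs <-
      unlist(raw$caregiver_probs)
  do.call(cohort_spec, raw)
}

## evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic two-arm cohort
#'
#' In calibrated mode (default) all integer quantities are allocated
#' deterministically by largest-remainder so that stage counts, diagnosis
#' counts, per-arm-per-stage mean visits, EBUS-uptake proportions,
#' treatment-receipt counts and under-65 counts match the specification
#' exactly (visit and utilization means up to 1/(2n) from rounding the target
#' sum to an integer); continuous fields (distance, age) are deterministic
#' distribution quantiles, with the distance mean matched exactly. In sampled
#' mode each field is drawn from its noise model (shifted truncated Poisson
#' visits, Poisson utilization counts, lognormal distances, truncated normal
#' ages, Bernoulli EBUS/treatment flags) under the given seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the RNG state of the session is left untouched.
#' @param calibrated logical; exact deterministic allocation (`TRUE`) or
#'   stochastic sampling (`FALSE`).
#' @return an `mdc_cohort` data.frame, one row per patient.
#' @examples
#' coh <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(coh$arm)
#' @export
generate_cohort <- function(spec, seed = 1L, calibrated = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  check_count(seed, "seed")
  gen <- function() {
    arms <- lapply(ARMS, function(a) generate_arm(spec, a, calibrated))
    out <- do.call(rbind, arms)
    rownames(out) <- NULL
    class(out) <- c("mdc_cohort", "data.frame")
    out
  }
  if (calibrated) gen() else with_seed(seed, gen())
}

generate_arm <- function(spec, arm, calibrated) {
  n <- as.integer(spec$n[[arm]])
  sp <- spec$stage_props[[arm]]
  if (calibrated) {
    stage_counts <- largest_remainder(n, sp)
  } else {
    stage_counts <- tabulate(
      sample.int(length(STAGES), n, replace = TRUE, prob = sp),
      nbins = length(STAGES))
  }
  stage <- rep(STAGES, stage_counts)

  visits <- integer(0)
  vm <- spec$visit_means[[arm]]
  for (i in seq_along(STAGES)) {
    ns <- stage_counts[i]
    if (ns == 0) next
    mu <- vm[[STAGES[i]]]
    if (calibrated) {
      v <- allocate_even(round(mu * ns), ns)
    } else {
      v <- 1L + stats::rpois(ns, max(mu - 1, 0))
    }
    visits <- c(visits, pmin(v, spec$visit_max))
  }

  if (calibrated) {
    diag_counts <- largest_remainder(n, spec$diagnosis_props[[arm]])
    diagnosis <- rep(DIAGNOSES, diag_counts)[deal_order(n)]
    biopsies <- allocate_even(round(spec$biopsy_mean[[arm]] * n), n)[deal_order(n)]
    imaging <- allocate_even(round(spec$imaging_mean[[arm]] * n), n)[deal_order(n)]
    caregivers <- rep(1:4, largest_remainder(n, spec$caregiver_probs))[deal_order(n)]
  } else {
    diagnosis <- DIAGNOSES[sample.int(length(DIAGNOSES), n, replace = TRUE,
                                      prob = spec$diagnosis_props[[arm]])]
    biopsies <- stats::rpois(n, spec$biopsy_mean[[arm]])
    imaging <- stats::rpois(n, spec$imaging_mean[[arm]])
    caregivers <- sample(1:4, n, replace = TRUE, prob = spec$caregiver_probs)
  }

  eligible <- stage %in% c("2", "3")
  ebus <- rep(FALSE, n)
  if (any(eligible)) {
    ne <- sum(eligible)
    if (calibrated) {
      k <- round(spec$ebus_prob[[arm]] * ne)
      ebus[which(eligible)[seq_len(k)]] <- TRUE
    } else {
      ebus[eligible] <- stats::runif(ne) < spec$ebus_prob[[arm]]
    }
  }

  distance <- gen_distance(n, spec$distance_mean_km[[arm]],
                           spec$distance_sdlog, calibrated)
  age <- gen_ages(n, spec$age_mean[[arm]], spec$age_sd[[arm]],
                  spec$under65_prop[[arm]], calibrated)

  treatments <- rep("", n)
  tr <- spec$treatment_rates
  for (r in seq_len(nrow(tr))) {
    idx <- which(stage == tr$stage[r])
    if (!length(idx)) next
    rate <- tr[[arm]][r]
    hit <- if (calibrated) idx[seq_len(round(rate * length(idx)))]
           else idx[stats::runif(length(idx)) < rate]
    toks <- strsplit(tr$treatment[r], ";", fixed = TRUE)[[1]]
    for (i in hit)
      treatments[i] <- paste(unique(c(
        strsplit(treatments[i], ";", fixed = TRUE)[[1]], toks)),
        collapse = ";")
  }
  treatments[treatments == ";"] <- ""
  treatments <- sub("^;", "", treatments)

  data.frame(
    patient_id = sprintf("%s-%04d", arm, seq_len(n)),
    arm = arm, diagnosis = diagnosis, stage = stage,
    oncology_visits = as.integer(visits), biopsies = as.integer(biopsies),
    staging_imaging = as.integer(imaging), ebus_performed = ebus,
    return_distance_km = distance, caregivers = as.integer(caregivers),
    age_years = age, treatments = treatments,
    stringsAsFactors = FALSE
  )
}

## a fixed "card-dealing" permutation that spreads sorted category labels
## evenly across the arm so calibrated categorical fields are not confounded
## with the stage blocks
deal_order <- function(n, k = 7L) order((seq_len(n) - 1L) %% k, seq_len(n))

gen_distance <- function(n, mean_km, sdlog, calibrated) {
  if (mean_km == 0) return(rep(0, n))
  meanlog <- log(mean_km) - sdlog^2 / 2
  if (calibrated) {
    p <- (seq_len(n) - 0.5) / n
    d <- stats::qlnorm(p, meanlog, sdlog)
    d <- d * mean_km / mean(d)          # hit the target mean exactly
    d[deal_order(n, 5L)]
  } else {
    stats::rlnorm(n, meanlog, sdlog)
  }
}

## ages truncated to [18, 100]; calibrated mode places exactly round(p65 * n)
## patients below 65 using conditional normal quantiles
gen_ages <- function(n, mu, sd, p65, calibrated) {
  lo <- stats::pnorm(18, mu, sd); mid <- stats::pnorm(65, mu, sd)
  hi <- stats::pnorm(100, mu, sd)
  if (calibrated) {
    k <- round(p65 * n)
    qs <- function(m, a, b) if (m == 0) numeric(0) else
      stats::qnorm(a + ((seq_len(m) - 0.5) / m) * (b - a), mu, sd)
    age <- c(qs(k, lo, mid), qs(n - k, mid, hi))
    age[deal_order(n, 3L)]
  } else {
    u <- stats::runif(n, lo, hi)
    stats::qnorm(u, mu, sd)
  }
}

#' Per-arm demographic and utilization summary of a cohort
#'
#' @param cohort an `mdc_cohort` data.frame (or any data.frame with the
#'   cohort schema).
#' @return a `cohort_summary` object: per-arm size, stage and diagnosis
#'   counts, mean age, mean return distance, mean caregivers per patient.
#' @export
summarize_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0)
    stop("cannot summarize an empty cohort", call. = FALSE)
  check_cohort(cohort)
  per_arm <- lapply(split(cohort, factor(cohort$arm, levels = ARMS)),
                    function(d) {
    if (nrow(d) == 0) return(NULL)
    list(
      n = nrow(d),
      stage_counts = table(factor(d$stage, levels = STAGES)),
      diagnosis_counts = table(factor(d$diagnosis, levels = DIAGNOSES)),
      mean_age = mean(d$age_years),
      mean_distance_km = mean(d$return_distance_km),
      mean_caregivers = mean(d$caregivers),
      n_under65 = sum(d$age_years < 65)
    )
  })
  structure(per_arm[!vapply(per_arm, is.null, logical(1))],
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (arm in names(x)) {
    s <- x[[arm]]
    cat(sprintf("Arm %s: n = %d, mean age %.1f y (%d under 65), mean return distance %.1f km, mean caregivers %.2f\n",
                arm, s$n, s$mean_age, s$n_under65, s$mean_distance_km,
                s$mean_caregivers))
    cat("  stage:     ", paste(sprintf("%s=%d", names(s$stage_counts),
                                       s$stage_counts), collapse = "  "), "\n")
    cat("  diagnosis: ", paste(sprintf("%s=%d", names(s$diagnosis_counts),
                                       s$diagnosis_counts), collapse = "  "),
        "\n")
  }
  invisible(x)
}

check_cohort <- function(cohort) {
  miss <- setdiff(cohort_columns, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!cohort$arm %in% ARMS))
    fail_field("arm", "values must be 'traditional' or 'mdc'")
  if (any(!cohort$stage %in% STAGES)) fail_field("stage", "unknown stage")
  if (any(cohort$caregivers < 1 | cohort$caregivers > 4))
    fail_field("caregivers", "must lie in [1, 4]")
  if (any(cohort$ebus_performed & !cohort$stage %in% c("2", "3")))
    fail_field("ebus_performed",
               "EBUS-TBNA may only be flagged for stage-2/3 patients")
  invisible(cohort)
}

#' Write / read a cohort as CSV
#'
#' The on-disk schema uses lowercase `true`/`false` booleans and
#' semicolon-joined treatment tokens, so files are portable outside R.
#'
#' @param cohort an `mdc_cohort` data.frame.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `mdc_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  out <- cohort[, cohort_columns]
  out$ebus_performed <- ifelse(out$ebus_performed, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(stage = "character",
                                      treatments = "character"))
  d$ebus_performed <- d$ebus_performed %in% c("true", "TRUE", "True")
  d$treatments[is.na(d$treatments)] <- ""
  check_cohort(d)
  class(d) <- c("mdc_cohort", "data.frame")
  d
}

## shared YAML/JSON reader for all config files
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext, call. = FALSE)
}
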