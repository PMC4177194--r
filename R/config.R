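# Scenario configuration: typed parameter bundles, validation, YAML I/O and
# the packaged reference scenarios.
#
# A scenario is one care arm (conventional or telemedical) applied to a
# cohort: per-NYHA-class event probabilities, outpatient tariffs, one LDF
# reimbursement group per class, an individual-medical-procedure catalogue
# and, for the telemedical arm, a financing scheme for the monitoring system.

NYHA_CLASSES <- 1:4
CARE_ARMS <- c("conventional", "telemedical")

# Coerce to a valid NYHA class (integer 1-4).
as_nyha <- function(x) {
  x <- as.integer(x)
  if (length(x) != 1 || is.na(x) || !(x %in% NYHA_CLASSES)) {
    stop("NYHA class must be one of 1, 2, 3, 4", call. = FALSE)
  }
  x
}

as_care_arm <- function(x) {
  x <- as.character(x)
  if (length(x) != 1 || !(x %in% CARE_ARMS)) {
    stop("care arm must be 'conventional' or 'telemedical'", call. = FALSE)
  }
  x
}

#' Per-NYHA-class event parameters
#'
#' Bundles every class-specific probability and rate driving a patient's
#' pathway: the daily worsening check and its downstream branches in
#' conventional care, the weekly alarm cascade in telemedical care, routine
#' visit rates, and the inpatient parameters (ICU involvement, procedures,
#' length of stay, in-hospital mortality, discharge NYHA transition).
#'
#' `worsening_prob_per_day` and `tm_alarm_prob_per_cycle` may be `NULL`, in
#' which case [scenario_config()] calibrates them so that the implied daily
#' admission hazard reproduces `period_hospitalization_prob` over the
#' scenario's reference period (see [calibrate_nyha_params()]).
#'
#' @param period_hospitalization_prob Probability of hospitalization per
#'   reference period (calibration target, e.g. 0.3208 per 182 days).
#' @param worsening_prob_per_day Daily probability that the outpatient's
#'   condition declines, or `NULL` to calibrate.
#' @param emergency_prob_given_worsening Probability that a worsening is an
#'   emergency requiring immediate transport.
#' @param medication_change_prob Probability (within the non-emergency
#'   branch) that only the medication is changed, without personal contact.
#' @param provider_choice_probs Named triple `(doctor, specialist,
#'   ambulance)`; together with `medication_change_prob` it must sum to 1.
#' @param improvement_prob_after_contact Probability the contact resolves
#'   the worsening.
#' @param hospitalization_prob_no_improvement Referral probability when no
#'   improvement is achieved.
#' @param extramural_mortality_prob Out-of-hospital death probability per
#'   failed-improvement cycle (only active when the scenario toggle is on).
#' @param gp_visits_per_year,specialist_visits_per_year Routine scheduled
#'   contact rates (visits per patient-year).
#' @param icu_admission_prob Probability an admission involves intensive care.
#' @param imp_prob Probability an admission includes an individual medical
#'   procedure; `imp_weights` is a named weight vector over catalogue codes.
#' @param imp_weights Named nonnegative weights over procedure codes.
#' @param los_ward_median_days,los_icu_median_days Median lengths of stay.
#' @param los_log_sigma Log-scale dispersion of the length-of-stay draw
#'   (see [sample_los()]).
#' @param in_hospital_mortality_prob Death probability per admission.
#' @param discharge_transition_probs Named triple `(improve, stay, worsen)`
#'   applied to the NYHA class at discharge.
#' @param tm_alarm_prob_per_cycle Weekly telemonitoring alarm probability,
#'   or `NULL` to calibrate (telemedical arm).
#' @param tm_intervention_success_prob Probability a remote intervention
#'   resolves the alarm.
#' @param tm_facetoface_adaptation_prob Probability a face-to-face contact
#'   resolves it.
#' @param tm_contact_choice_probs Named triple `(home_visit, doctor_visit,
#'   hospitalization)` summing to 1.
#' @return A list of class `hf_nyha_params`.
#' @export
nyha_parameters <- function(period_hospitalization_prob,
                            worsening_prob_per_day = NULL,
                            emergency_prob_given_worsening = 0.10,
                            medication_change_prob = 0.20,
                            provider_choice_probs = c(doctor = 0.40,
                                                      specialist = 0.25,
                                                      ambulance = 0.15),
                            improvement_prob_after_contact = 0.60,
                            hospitalization_prob_no_improvement = 0.50,
                            extramural_mortality_prob = 0.02,
                            gp_visits_per_year = 0,
                            specialist_visits_per_year = 0,
                            icu_admission_prob = 0,
                            imp_prob = 0,
                            imp_weights = c(`IMP-A` = 1),
                            los_ward_median_days = 10,
                            los_icu_median_days = 2,
                            los_log_sigma = 0.5,
                            in_hospital_mortality_prob = 0,
                            discharge_transition_probs = c(improve = 0.40,
                                                           stay = 0.45,
                                                           worsen = 0.15),
                            tm_alarm_prob_per_cycle = NULL,
                            tm_intervention_success_prob = 0.70,
                            tm_facetoface_adaptation_prob = 0.70,
                            tm_contact_choice_probs = c(home_visit = 0.40,
                                                        doctor_visit = 0.40,
                                                        hospitalization = 0.20)) {
  out <- list(
    period_hospitalization_prob = period_hospitalization_prob,
    worsening_prob_per_day = worsening_prob_per_day,
    emergency_prob_given_worsening = emergency_prob_given_worsening,
    medication_change_prob = medication_change_prob,
    provider_choice_probs = provider_choice_probs,
    improvement_prob_after_contact = improvement_prob_after_contact,
    hospitalization_prob_no_improvement = hospitalization_prob_no_improvement,
    extramural_mortality_prob = extramural_mortality_prob,
    gp_visits_per_year = gp_visits_per_year,
    specialist_visits_per_year = specialist_visits_per_year,
    icu_admission_prob = icu_admission_prob,
    imp_prob = imp_prob,
    imp_weights = imp_weights,
    los_ward_median_days = los_ward_median_days,
    los_icu_median_days = los_icu_median_days,
    los_log_sigma = los_log_sigma,
    in_hospital_mortality_prob = in_hospital_mortality_prob,
    discharge_transition_probs = discharge_transition_probs,
    tm_alarm_prob_per_cycle = tm_alarm_prob_per_cycle,
    tm_intervention_success_prob = tm_intervention_success_prob,
    tm_facetoface_adaptation_prob = tm_facetoface_adaptation_prob,
    tm_contact_choice_probs = tm_contact_choice_probs
  )
  class(out) <- "hf_nyha_params"
  out
}

#' Outpatient tariffs and the point-to-euro conversion factor
#'
#' @param gp_visit_eur,specialist_visit_eur,ambulance_visit_eur,home_visit_eur
#'   Per-contact tariffs in euros.
#' @param emergency_transport_eur,medication_event_eur Per-event tariffs.
#' @param euro_per_ldf_point Conversion factor from LDF points to euros
#'   (adjustable; the packaged scenarios use 1 so point scores read as euros).
#' @return A list of class `hf_tariffs`.
#' @export
cost_tariffs <- function(gp_visit_eur = 25,
                         specialist_visit_eur = 31,
                         ambulance_visit_eur = 40,
                         home_visit_eur = 45,
                         emergency_transport_eur = 150,
                         medication_event_eur = 30,
                         euro_per_ldf_point = 1) {
  out <- list(
    gp_visit_eur = gp_visit_eur,
    specialist_visit_eur = specialist_visit_eur,
    ambulance_visit_eur = ambulance_visit_eur,
    home_visit_eur = home_visit_eur,
    emergency_transport_eur = emergency_transport_eur,
    medication_event_eur = medication_event_eur,
    euro_per_ldf_point = euro_per_ldf_point
  )
  class(out) <- "hf_tariffs"
  out
}

#' LDF case-group reimbursement parameters
#'
#' Austrian DRG-style case flat rate: stays whose total length falls between
#' the trim points earn `flat_points`; each day beyond `trim_max_days` adds
#' `daily_supplement_points`; stays shorter than `trim_min_days` earn a
#' reduced flat rate. ICU days earn a daily supplementary score on top.
#'
#' @param flat_points Case flat rate in LDF points.
#' @param trim_min_days,trim_max_days Trim points in days (heart failure
#'   default 4 and 12).
#' @param daily_supplement_points Points per day beyond `trim_max_days`.
#' @param reduced_flat_fraction Fraction of the flat rate paid when the stay
#'   is shorter than `trim_min_days` (in `(0, 1]`).
#' @param icu_daily_supplement_points Points per intensive-care day.
#' @return A list of class `hf_ldf_group`.
#' @export
ldf_group <- function(flat_points = 1523,
                      trim_min_days = 4,
                      trim_max_days = 12,
                      daily_supplement_points = 100,
                      reduced_flat_fraction = 0.5,
                      icu_daily_supplement_points = 1248) {
  out <- list(
    flat_points = flat_points,
    trim_min_days = as.integer(trim_min_days),
    trim_max_days = as.integer(trim_max_days),
    daily_supplement_points = daily_supplement_points,
    reduced_flat_fraction = reduced_flat_fraction,
    icu_daily_supplement_points = icu_daily_supplement_points
  )
  class(out) <- "hf_ldf_group"
  out
}

#' Telemonitoring financing scheme
#'
#' Variant A folds equipment lease, maintenance and physician effort into one
#' monthly rate per patient. Variant B splits them: an acquisition cost per
#' monitoring system, a cohort-level monthly overhead for running the
#' service, and a per-patient monthly physician fee.
#'
#' @param variant `"A"` or `"B"`.
#' @param monthly_rate_per_patient_eur Variant-A all-in monthly rate.
#' @param acquisition_per_system_eur,monthly_overhead_eur,physician_fee_per_patient_month_eur
#'   Variant-B components.
#' @return A list of class `hf_financing`.
#' @export
telemed_financing <- function(variant = c("A", "B"),
                              monthly_rate_per_patient_eur = 100,
                              acquisition_per_system_eur = 1000,
                              monthly_overhead_eur = 500,
                              physician_fee_per_patient_month_eur = 40) {
  variant <- match.arg(variant)
  out <- list(
    variant = variant,
    monthly_rate_per_patient_eur = monthly_rate_per_patient_eur,
    acquisition_per_system_eur = acquisition_per_system_eur,
    monthly_overhead_eur = monthly_overhead_eur,
    physician_fee_per_patient_month_eur = physician_fee_per_patient_month_eur
  )
  class(out) <- "hf_financing"
  out
}

# Probability that one worsening day ends in a hospital admission, given the
# configured branch probabilities and scenario toggles (conventional arm).
p_admission_given_worsening <- function(params, toggles) {
  e <- params$emergency_prob_given_worsening
  i <- params$improvement_prob_after_contact
  h <- params$hospitalization_prob_no_improvement
  m <- if (isTRUE(toggles$extramural_mortality)) params$extramural_mortality_prob else 0
  e + (1 - e) * (1 - i) * (1 - m) * h
}

# Probability that one alarm-raising control cycle ends in an admission
# (telemedical arm).
p_admission_given_alarm <- function(params, toggles) {
  e <- params$emergency_prob_given_worsening
  s <- params$tm_intervention_success_prob
  cc <- params$tm_contact_choice_probs
  a <- params$tm_facetoface_adaptation_prob
  h <- params$hospitalization_prob_no_improvement
  m <- if (isTRUE(toggles$extramural_mortality)) params$extramural_mortality_prob else 0
  face <- cc[["home_visit"]] + cc[["doctor_visit"]]
  e + (1 - e) * (1 - s) *
    (cc[["hospitalization"]] + face * (1 - a) * (1 - m) * h)
}

#' Calibrate pathway trigger probabilities to the period hospitalization rate
#'
#' Fills `worsening_prob_per_day` (conventional arm) or
#' `tm_alarm_prob_per_cycle` (telemedical arm) when they are `NULL`, choosing
#' the value for which the pathway's daily admission hazard equals
#' `daily_hazard_from_period_prob(period_hospitalization_prob,
#' reference_period_days)`. Values supplied explicitly are left untouched.
#'
#' @param params An [nyha_parameters()] bundle.
#' @param arm `"conventional"` or `"telemedical"`.
#' @param reference_period_days Length of the reference period (days).
#' @param toggles Scenario toggles (the extramural-mortality toggle enters
#'   the admission probability of the no-improvement branch).
#' @return The bundle with trigger probabilities filled in.
#' @export
calibrate_nyha_params <- function(params, arm, reference_period_days,
                                  toggles = list()) {
  arm <- as_care_arm(arm)
  p <- params$period_hospitalization_prob
  if (arm == "conventional" && is.null(params$worsening_prob_per_day)) {
    hd <- daily_hazard_from_period_prob(p, reference_period_days)
    params$worsening_prob_per_day <- hd / p_admission_given_worsening(params, toggles)
  }
  if (arm == "telemedical" && is.null(params$tm_alarm_prob_per_cycle)) {
    hw <- 1 - (1 - p)^(7 / reference_period_days)
    params$tm_alarm_prob_per_cycle <- hw / p_admission_given_alarm(params, toggles)
  }
  if (is.null(params$worsening_prob_per_day)) params$worsening_prob_per_day <- 0
  if (is.null(params$tm_alarm_prob_per_cycle)) params$tm_alarm_prob_per_cycle <- 0
  params
}

#' Assemble and validate a scenario configuration
#'
#' @param arm Care arm, `"conventional"` or `"telemedical"`.
#' @param n_patients Cohort size.
#' @param nyha_distribution Four fractions (classes 1-4) summing to 1.
#' @param horizon_days Simulated horizon in days (one time step = one day).
#' @param n_runs Number of independent runs averaged by [run_scenario()].
#' @param seed Base seed; every substream is derived from it.
#' @param reference_period_days Period over which
#'   `period_hospitalization_prob` is expressed (default 182 days = the
#'   6-month follow-up of the source telemonitoring trial).
#' @param nyha_params List of four [nyha_parameters()] bundles (classes 1-4).
#' @param tariffs A [cost_tariffs()] object.
#' @param ldf List of four [ldf_group()] objects (classes 1-4).
#' @param imp_catalogue Tibble with columns `code`, `points`.
#' @param financing A [telemed_financing()] object (telemedical arm only).
#' @param toggles Named logical list: `ambulance_costs`, `medication_costs`,
#'   `transport_costs`, `extramural_mortality`. The packaged scenarios
#'   disable all four.
#' @param label Free-text scenario label.
#' @return A validated list of class `hf_scenario`.
#' @export
scenario_config <- function(arm,
                            n_patients,
                            nyha_distribution,
                            horizon_days,
                            n_runs = 10,
                            seed = 1,
                            reference_period_days = 182,
                            nyha_params,
                            tariffs = cost_tariffs(),
                            ldf = rep(list(ldf_group()), 4),
                            imp_catalogue = tibble::tibble(
                              code = c("IMP-A", "IMP-B"),
                              points = c(2500, 5000)
                            ),
                            financing = NULL,
                            toggles = list(ambulance_costs = FALSE,
                                           medication_costs = FALSE,
                                           transport_costs = FALSE,
                                           extramural_mortality = FALSE),
                            label = arm) {
  arm <- as_care_arm(arm)
  if (inherits(nyha_params, "hf_nyha_params")) {
    nyha_params <- rep(list(nyha_params), 4)
  }
  default_toggles <- list(ambulance_costs = FALSE, medication_costs = FALSE,
                          transport_costs = FALSE, extramural_mortality = FALSE)
  toggles <- utils::modifyList(default_toggles, toggles)
  nyha_params <- purrr::map(nyha_params, calibrate_nyha_params,
                            arm = arm,
                            reference_period_days = reference_period_days,
                            toggles = toggles)
  if (arm == "telemedical" && is.null(financing)) {
    stop("telemedical scenarios need a `financing` scheme", call. = FALSE)
  }
  cfg <- list(
    schema_version = 1L,
    label = label,
    arm = arm,
    n_patients = as.integer(n_patients),
    nyha_distribution = as.numeric(nyha_distribution),
    horizon_days = as.integer(horizon_days),
    n_runs = as.integer(n_runs),
    seed = as.integer(seed),
    reference_period_days = as.integer(reference_period_days),
    nyha_params = nyha_params,
    tariffs = tariffs,
    ldf = ldf,
    imp_catalogue = tibble::as_tibble(imp_catalogue),
    financing = financing,
    toggles = toggles
  )
  class(cfg) <- "hf_scenario"
  v <- validate_scenario(cfg)
  if (nrow(v) > 0) {
    stop("invalid scenario configuration:\n",
         paste0("  - ", v$field, " = ", v$value, ": ", v$constraint,
                collapse = "\n"),
         call. = FALSE)
  }
  cfg
}

#' @export
print.hf_scenario <- function(x, ...) {
  cat(sprintf("<hf_scenario '%s'> arm=%s, %d patients, %d days, %d runs, seed=%d\n",
              x$label, x$arm, x$n_patients, x$horizon_days, x$n_runs, x$seed))
  cat(sprintf("  NYHA distribution: %s\n",
              paste(format(x$nyha_distribution), collapse = " / ")))
  if (!is.null(x$financing)) {
    cat(sprintf("  financing: variant %s\n", x$financing$variant))
  }
  invisible(x)
}

# One violation row.
.viol <- function(field, value, constraint) {
  tibble::tibble(field = field,
                 value = paste(format(value), collapse = ","),
                 constraint = constraint)
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    .viol(field, x, "must be a probability in [0, 1]")
  } else {
    NULL
  }
}

.check_sum1 <- function(x, field) {
  if (abs(sum(x) - 1) > 1e-9) .viol(field, sum(x), "must sum to 1") else NULL
}

# Violations for one per-class parameter bundle; `prefix` names the class.
validate_nyha_params <- function(p, prefix = "nyha_params") {
  f <- function(name) paste0(prefix, ".", name)
  v <- list(
    .check_prob(p$period_hospitalization_prob, f("period_hospitalization_prob")),
    .check_prob(p$worsening_prob_per_day, f("worsening_prob_per_day")),
    .check_prob(p$emergency_prob_given_worsening, f("emergency_prob_given_worsening")),
    .check_prob(p$medication_change_prob, f("medication_change_prob")),
    .check_prob(p$provider_choice_probs, f("provider_choice_probs")),
    .check_sum1(c(p$medication_change_prob, p$provider_choice_probs),
                f("medication_change_prob + provider_choice_probs")),
    .check_prob(p$improvement_prob_after_contact, f("improvement_prob_after_contact")),
    .check_prob(p$hospitalization_prob_no_improvement, f("hospitalization_prob_no_improvement")),
    .check_prob(p$extramural_mortality_prob, f("extramural_mortality_prob")),
    .check_prob(p$icu_admission_prob, f("icu_admission_prob")),
    .check_prob(p$imp_prob, f("imp_prob")),
    .check_prob(p$in_hospital_mortality_prob, f("in_hospital_mortality_prob")),
    .check_prob(p$discharge_transition_probs, f("discharge_transition_probs")),
    .check_sum1(p$discharge_transition_probs, f("discharge_transition_probs")),
    .check_prob(p$tm_alarm_prob_per_cycle, f("tm_alarm_prob_per_cycle")),
    .check_prob(p$tm_intervention_success_prob, f("tm_intervention_success_prob")),
    .check_prob(p$tm_facetoface_adaptation_prob, f("tm_facetoface_adaptation_prob")),
    .check_prob(p$tm_contact_choice_probs, f("tm_contact_choice_probs")),
    .check_sum1(p$tm_contact_choice_probs, f("tm_contact_choice_probs"))
  )
  if (p$gp_visits_per_year < 0) {
    v <- c(v, list(.viol(f("gp_visits_per_year"), p$gp_visits_per_year, "must be >= 0")))
  }
  if (p$specialist_visits_per_year < 0) {
    v <- c(v, list(.viol(f("specialist_visits_per_year"),
                         p$specialist_visits_per_year, "must be >= 0")))
  }
  if (any(p$imp_weights < 0)) {
    v <- c(v, list(.viol(f("imp_weights"), p$imp_weights, "must be >= 0")))
  }
  if (p$los_ward_median_days < 1) {
    v <- c(v, list(.viol(f("los_ward_median_days"), p$los_ward_median_days,
                         "must be >= 1 day")))
  }
  if (p$los_icu_median_days < 1) {
    v <- c(v, list(.viol(f("los_icu_median_days"), p$los_icu_median_days,
                         "must be >= 1 day")))
  }
  if (p$los_log_sigma < 0) {
    v <- c(v, list(.viol(f("los_log_sigma"), p$los_log_sigma, "must be >= 0")))
  }
  dplyr::bind_rows(v)
}

validate_ldf <- function(l, prefix = "ldf") {
  f <- function(name) paste0(prefix, ".", name)
  v <- list()
  if (l$flat_points <= 0) {
    v <- c(v, list(.viol(f("flat_points"), l$flat_points, "must be > 0")))
  }
  if (l$trim_min_days < 1) {
    v <- c(v, list(.viol(f("trim_min_days"), l$trim_min_days, "must be >= 1")))
  }
  if (l$trim_max_days < l$trim_min_days) {
    v <- c(v, list(.viol(f("trim_max_days"), l$trim_max_days,
                         "must be >= trim_min_days")))
  }
  if (l$daily_supplement_points < 0) {
    v <- c(v, list(.viol(f("daily_supplement_points"), l$daily_supplement_points,
                         "must be >= 0")))
  }
  if (l$icu_daily_supplement_points < 0) {
    v <- c(v, list(.viol(f("icu_daily_supplement_points"),
                         l$icu_daily_supplement_points, "must be >= 0")))
  }
  if (l$reduced_flat_fraction <= 0 || l$reduced_flat_fraction > 1) {
    v <- c(v, list(.viol(f("reduced_flat_fraction"), l$reduced_flat_fraction,
                         "must be in (0, 1]")))
  }
  dplyr::bind_rows(v)
}

#' Validate a scenario configuration
#'
#' Checks every type invariant and returns the violations as a tibble with
#' columns `field`, `value`, `constraint` (empty when the configuration is
#' valid). Reports rather than throws, so it can be used to lint
#' hand-written configuration files.
#'
#' @param cfg An `hf_scenario`, e.g. from [load_scenario()].
#' @return A tibble of violations; zero rows iff the configuration is valid.
#' @export
validate_scenario <- function(cfg) {
  v <- list()
  if (!(cfg$arm %in% CARE_ARMS)) {
    v <- c(v, list(.viol("arm", cfg$arm, "must be 'conventional' or 'telemedical'")))
  }
  if (cfg$n_patients < 1) {
    v <- c(v, list(.viol("n_patients", cfg$n_patients, "must be >= 1")))
  }
  if (length(cfg$nyha_distribution) != 4 || any(cfg$nyha_distribution < 0) ||
      abs(sum(cfg$nyha_distribution) - 1) > 1e-9) {
    v <- c(v, list(.viol("nyha_distribution", cfg$nyha_distribution,
                         "must be four nonnegative fractions summing to 1")))
  }
  if (cfg$horizon_days < 1) {
    v <- c(v, list(.viol("horizon_days", cfg$horizon_days, "must be >= 1")))
  }
  if (cfg$n_runs < 1) {
    v <- c(v, list(.viol("n_runs", cfg$n_runs, "must be >= 1")))
  }
  if (cfg$reference_period_days < 1) {
    v <- c(v, list(.viol("reference_period_days", cfg$reference_period_days,
                         "must be >= 1")))
  }
  for (k in 1:4) {
    v <- c(v, list(validate_nyha_params(cfg$nyha_params[[k]],
                                        sprintf("nyha_params[%d]", k))))
    v <- c(v, list(validate_ldf(cfg$ldf[[k]], sprintf("ldf[%d]", k))))
  }
  tr <- cfg$tariffs
  for (fld in c("gp_visit_eur", "specialist_visit_eur", "ambulance_visit_eur",
                "home_visit_eur", "emergency_transport_eur",
                "medication_event_eur")) {
    if (tr[[fld]] < 0) {
      v <- c(v, list(.viol(paste0("tariffs.", fld), tr[[fld]], "must be >= 0")))
    }
  }
  if (tr$euro_per_ldf_point <= 0) {
    v <- c(v, list(.viol("tariffs.euro_per_ldf_point", tr$euro_per_ldf_point,
                         "must be > 0")))
  }
  if (any(cfg$imp_catalogue$points <= 0)) {
    v <- c(v, list(.viol("imp_catalogue.points", cfg$imp_catalogue$points,
                         "must be > 0")))
  }
  if (anyDuplicated(cfg$imp_catalogue$code)) {
    v <- c(v, list(.viol("imp_catalogue.code", cfg$imp_catalogue$code,
                         "codes must be unique")))
  }
  if (cfg$arm == "telemedical") {
    if (is.null(cfg$financing)) {
      v <- c(v, list(.viol("financing", "NULL",
                           "telemedical scenarios need a financing scheme")))
    } else {
      fin <- cfg$financing
      if (!(fin$variant %in% c("A", "B"))) {
        v <- c(v, list(.viol("financing.variant", fin$variant, "must be 'A' or 'B'")))
      }
      for (fld in c("monthly_rate_per_patient_eur", "acquisition_per_system_eur",
                    "monthly_overhead_eur", "physician_fee_per_patient_month_eur")) {
        if (fin[[fld]] < 0) {
          v <- c(v, list(.viol(paste0("financing.", fld), fin[[fld]],
                               "must be >= 0")))
        }
      }
    }
  }
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    out <- tibble::tibble(field = character(), value = character(),
                          constraint = character())
  }
  out
}

# ---- YAML serialisation ------------------------------------------------------

.params_to_list <- function(p) {
  list(
    period_hospitalization_prob = p$period_hospitalization_prob,
    worsening_prob_per_day = p$worsening_prob_per_day,
    emergency_prob_given_worsening = p$emergency_prob_given_worsening,
    medication_change_prob = p$medication_change_prob,
    provider_choice_probs = as.list(p$provider_choice_probs),
    improvement_prob_after_contact = p$improvement_prob_after_contact,
    hospitalization_prob_no_improvement = p$hospitalization_prob_no_improvement,
    extramural_mortality_prob = p$extramural_mortality_prob,
    gp_visits_per_year = p$gp_visits_per_year,
    specialist_visits_per_year = p$specialist_visits_per_year,
    icu_admission_prob = p$icu_admission_prob,
    imp_prob = p$imp_prob,
    imp_weights = as.list(p$imp_weights),
    los_ward_median_days = p$los_ward_median_days,
    los_icu_median_days = p$los_icu_median_days,
    los_log_sigma = p$los_log_sigma,
    in_hospital_mortality_prob = p$in_hospital_mortality_prob,
    discharge_transition_probs = as.list(p$discharge_transition_probs),
    tm_alarm_prob_per_cycle = p$tm_alarm_prob_per_cycle,
    tm_intervention_success_prob = p$tm_intervention_success_prob,
    tm_facetoface_adaptation_prob = p$tm_facetoface_adaptation_prob,
    tm_contact_choice_probs = as.list(p$tm_contact_choice_probs)
  )
}

.params_from_list <- function(x, where) {
  known <- names(formals(nyha_parameters))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key '%s' in %s", unknown[1], where), call. = FALSE)
  }
  for (fld in c("provider_choice_probs", "discharge_transition_probs",
                "tm_contact_choice_probs", "imp_weights")) {
    if (!is.null(x[[fld]])) x[[fld]] <- unlist(x[[fld]])
  }
  do.call(nyha_parameters, x)
}

#' Read a scenario configuration file
#'
#' Parses a YAML scenario file, fills documented defaults for omitted
#' optional keys (`n_runs = 10`, `seed = 1`, `reference_period_days = 182`,
#' all cost toggles off), calibrates omitted pathway trigger probabilities
#' (see [calibrate_nyha_params()]) and validates the result. Per-class
#' blocks may be written once under `nyha_params.shared` / `ldf.shared` with
#' optional `class_1` ... `class_4` overrides.
#'
#' @param path Path to a YAML scenario file.
#' @return A validated `hf_scenario`.
#' @seealso [write_scenario()], [reference_scenarios()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scenario file '%s' does not exist", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  known <- c("schema_version", "label", "arm", "n_patients",
             "nyha_distribution", "horizon_days", "n_runs", "seed",
             "reference_period_days", "nyha_params", "tariffs", "ldf",
             "imp_catalogue", "financing", "toggles")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key '%s' in scenario file", unknown[1]), call. = FALSE)
  }
  for (req in c("arm", "n_patients", "nyha_distribution", "horizon_days",
                "nyha_params")) {
    if (is.null(raw[[req]])) {
      stop(sprintf("scenario file is missing required key '%s'", req),
           call. = FALSE)
    }
  }

  # Expand shared-plus-override per-class blocks.
  expand_classes <- function(block, from_list, where) {
    if (!is.null(block$shared) || any(grepl("^class_[1-4]$", names(block)))) {
      shared <- block$shared %||% list()
      purrr::map(1:4, function(k) {
        override <- block[[paste0("class_", k)]] %||% list()
        from_list(utils::modifyList(shared, override), where)
      })
    } else {
      # A single flat block applies to all four classes.
      rep(list(from_list(block, where)), 4)
    }
  }
  nyha_params <- expand_classes(raw$nyha_params, .params_from_list, "nyha_params")
  ldf_from_list <- function(x, where) {
    unknown <- setdiff(names(x), names(formals(ldf_group)))
    if (length(unknown) > 0) {
      stop(sprintf("unknown key '%s' in %s", unknown[1], where), call. = FALSE)
    }
    do.call(ldf_group, x)
  }
  ldf <- expand_classes(raw$ldf %||% list(), ldf_from_list, "ldf")

  tariffs <- do.call(cost_tariffs, raw$tariffs %||% list())
  imp <- if (is.null(raw$imp_catalogue)) {
    tibble::tibble(code = c("IMP-A", "IMP-B"), points = c(2500, 5000))
  } else {
    dplyr::bind_rows(purrr::map(raw$imp_catalogue, tibble::as_tibble))
  }
  financing <- if (!is.null(raw$financing)) {
    do.call(telemed_financing, raw$financing)
  }
  scenario_config(
    arm = raw$arm,
    n_patients = raw$n_patients,
    nyha_distribution = unlist(raw$nyha_distribution),
    horizon_days = raw$horizon_days,
    n_runs = raw$n_runs %||% 10,
    seed = raw$seed %||% 1,
    reference_period_days = raw$reference_period_days %||% 182,
    nyha_params = nyha_params,
    tariffs = tariffs,
    ldf = ldf,
    imp_catalogue = imp,
    financing = financing,
    toggles = raw$toggles %||% list(),
    label = raw$label %||% raw$arm
  )
}

#' Write a scenario configuration file
#'
#' Serialises a scenario to YAML in the fully expanded per-class form.
#' `load_scenario(write_scenario(cfg, f))` reproduces `cfg` on every field.
#'
#' @param cfg An `hf_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(cfg, path) {
  out <- list(
    schema_version = cfg$schema_version,
    label = cfg$label,
    arm = cfg$arm,
    n_patients = cfg$n_patients,
    nyha_distribution = cfg$nyha_distribution,
    horizon_days = cfg$horizon_days,
    n_runs = cfg$n_runs,
    seed = cfg$seed,
    reference_period_days = cfg$reference_period_days,
    nyha_params = stats::setNames(
      purrr::map(cfg$nyha_params, .params_to_list), paste0("class_", 1:4)),
    tariffs = unclass(cfg$tariffs),
    ldf = stats::setNames(
      purrr::map(cfg$ldf, unclass), paste0("class_", 1:4)),
    imp_catalogue = purrr::pmap(cfg$imp_catalogue,
                                function(code, points) list(code = code,
                                                            points = points)),
    toggles = cfg$toggles
  )
  if (!is.null(cfg$financing)) out$financing <- unclass(cfg$financing)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' The packaged reference scenarios
#'
#' Loads the three scenario files shipped with the package: conventional
#' care, telemedical care under financing variant A (100 EUR per patient per
#' month) and telemedical care under financing variant B (1000 EUR
#' acquisition per system, 500 EUR monthly cohort overhead, 40 EUR per
#' patient per month physician fee). All three use a 100-patient cohort over
#' three years (NYHA distribution 0/61/37/2 %), averaged over 10 runs, with
#' ambulance, medication, transport and extramural-mortality costs disabled.
#' Event probabilities not available from published sources are labelled
#' `assumption` in the files and documented in the methods vignette.
#'
#' @return Named list with elements `conventional`, `tm_a`, `tm_b`.
#' @export
reference_scenarios <- function() {
  f <- function(name) {
    system.file("extdata", name, package = "telehf", mustWork = TRUE)
  }
  list(
    conventional = load_scenario(f("scenario_conventional.yaml")),
    tm_a = load_scenario(f("scenario_tm_a.yaml")),
    tm_b = load_scenario(f("scenario_tm_b.yaml"))
  )
}
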