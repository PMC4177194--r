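# Conventional outpatient care: the daily worsening check and its branches.
#
# Each patient-day resolves to exactly one outcome. A worsening either
# escalates immediately to an emergency admission or leads to a medication
# change or a contact (GP, specialist, ambulance); if the contact does not
# improve the condition, the cycle can end in extramural death (when that
# toggle is on), a referral admission, or carry over with the contact as the
# day's outcome.

CONVENTIONAL_OUTCOMES <- c("none", "medication_change", "gp_visit",
                           "specialist_visit", "ambulance_visit",
                           "emergency_admission", "referral_admission",
                           "extramural_death")

#' One conventional-care outpatient day
#'
#' Runs the daily decision chain for one outpatient: worsening draw at
#' `worsening_prob_per_day`; on worsening, an emergency draw
#' (`emergency_prob_given_worsening`) escalating straight to admission;
#' otherwise a choice between a medication change and the three provider
#' contacts; then an improvement draw (`improvement_prob_after_contact`);
#' on failure, extramural death (if the scenario toggle is on), else a
#' referral admission at `hospitalization_prob_no_improvement`, else the
#' day's outcome is the contact that occurred.
#'
#' @param patient An [patient_state()]; must be alive and outpatient.
#' @param params The patient's class-specific [nyha_parameters()].
#' @param toggles Scenario toggles (only `extramural_mortality` is read).
#' @param rng An [rng_stream()].
#' @param day Simulation day stamp (default 0).
#' @return A list with `kind` (one of `r paste(CONVENTIONAL_OUTCOMES,
#'   collapse = ", ")`) and `day`.
#' @export
conventional_daily_cycle <- function(patient, params, toggles = list(),
                                     rng, day = 0L) {
  if (patient$status != "outpatient") {
    stop("patient must be alive and in outpatient care", call. = FALSE)
  }
  outcome <- function(kind) list(kind = kind, day = as.integer(day))
  if (!draw_bernoulli(params$worsening_prob_per_day, rng)) {
    return(outcome("none"))
  }
  if (draw_bernoulli(params$emergency_prob_given_worsening, rng)) {
    return(outcome("emergency_admission"))
  }
  branch <- draw_categorical(
    c(params$medication_change_prob, params$provider_choice_probs), rng)
  contact <- c("medication_change", "gp_visit", "specialist_visit",
               "ambulance_visit")[branch]
  if (draw_bernoulli(params$improvement_prob_after_contact, rng)) {
    return(outcome(contact))
  }
  if (isTRUE(toggles$extramural_mortality) &&
      draw_bernoulli(params$extramural_mortality_prob, rng)) {
    return(outcome("extramural_death"))
  }
  if (draw_bernoulli(params$hospitalization_prob_no_improvement, rng)) {
    return(outcome("referral_admission"))
  }
  outcome(contact)
}

#' Schedule routine GP and specialist visits
#'
#' Routine scheduled contacts are drawn as a homogeneous Poisson process at
#' `gp_visits_per_year` and `specialist_visits_per_year` over the horizon,
#' independently of worsening-triggered contacts. Counts are drawn by
#' inverse-CDF so a schedule always consumes the same number of uniforms.
#'
#' @param params An [nyha_parameters()] bundle.
#' @param horizon_days Length of the schedule in days.
#' @param rng An [rng_stream()].
#' @return A tibble with columns `day` (integer in `[0, horizon_days)`) and
#'   `kind` (`"gp_visit"` or `"specialist_visit"`), sorted by day.
#' @export
schedule_routine_visits <- function(params, horizon_days, rng) {
  stopifnot(horizon_days >= 0)
  one <- function(rate, kind) {
    lambda <- rate * horizon_days / 365
    n <- stats::qpois(stream_next(rng), lambda)
    if (n == 0) {
      return(tibble::tibble(day = integer(0), kind = character(0)))
    }
    days <- as.integer(floor(stream_runif(rng, n) * horizon_days))
    tibble::tibble(day = days, kind = kind)
  }
  dplyr::arrange(
    dplyr::bind_rows(one(params$gp_visits_per_year, "gp_visit"),
                     one(params$specialist_visits_per_year, "specialist_visit")),
    .data$day)
}
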