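# Telemedical outpatient care: daily transmission of vital data (weight,
# blood pressure, heart rate, medication) is cost-free bookkeeping; the
# branching happens in the weekly control cycle at the telemedicine centre.

TELEMED_OUTCOMES <- c("none", "intervention", "home_visit", "doctor_visit",
                      "emergency_admission", "referral_admission",
                      "extramural_death")

#' One weekly telemonitoring control cycle
#'
#' Runs the alarm cascade for one monitored outpatient: alarm draw at
#' `tm_alarm_prob_per_cycle`; on alarm, an emergency draw escalating
#' straight to admission; otherwise a remote intervention attempt
#' (`tm_intervention_success_prob`); on failure a face-to-face contact is
#' chosen from `tm_contact_choice_probs` (home visit, doctor visit, or
#' direct hospitalization); after a face-to-face contact, treatment
#' adaptation succeeds at `tm_facetoface_adaptation_prob`, else the cycle
#' ends in extramural death (if the toggle is on) or a referral admission at
#' `hospitalization_prob_no_improvement`, else carries over with the contact
#' as the outcome. After any alarm-raising cycle the NYHA class is updated
#' with the configured transition probabilities.
#'
#' @inheritParams conventional_daily_cycle
#' @return A list with `kind` (one of `r paste(TELEMED_OUTCOMES,
#'   collapse = ", ")`), `day`, and `nyha_after` (the possibly updated
#'   class; unchanged for alarm-free cycles).
#' @export
telemedical_control_cycle <- function(patient, params, toggles = list(),
                                      rng, day = 0L) {
  if (patient$status != "outpatient") {
    stop("patient must be alive and in outpatient care", call. = FALSE)
  }
  nyha_after <- patient$nyha
  outcome <- function(kind, transition = TRUE) {
    if (transition && kind != "extramural_death") {
      nyha_after <<- sample_nyha_transition(
        patient$nyha, params$discharge_transition_probs, rng)
    }
    list(kind = kind, day = as.integer(day), nyha_after = nyha_after)
  }
  if (!draw_bernoulli(params$tm_alarm_prob_per_cycle, rng)) {
    return(list(kind = "none", day = as.integer(day), nyha_after = nyha_after))
  }
  if (draw_bernoulli(params$emergency_prob_given_worsening, rng)) {
    # NYHA change for admissions happens at discharge, in the inpatient block.
    return(outcome("emergency_admission", transition = FALSE))
  }
  if (draw_bernoulli(params$tm_intervention_success_prob, rng)) {
    return(outcome("intervention"))
  }
  contact <- draw_categorical(params$tm_contact_choice_probs, rng)
  if (contact == 3L) {
    return(outcome("referral_admission", transition = FALSE))
  }
  kind <- c("home_visit", "doctor_visit")[contact]
  if (draw_bernoulli(params$tm_facetoface_adaptation_prob, rng)) {
    return(outcome(kind))
  }
  if (isTRUE(toggles$extramural_mortality) &&
      draw_bernoulli(params$extramural_mortality_prob, rng)) {
    return(outcome("extramural_death", transition = FALSE))
  }
  if (draw_bernoulli(params$hospitalization_prob_no_improvement, rng)) {
    return(outcome("referral_admission", transition = FALSE))
  }
  outcome(kind)
}

#' Routine visit schedule for the telemedical arm
#'
#' Identical mechanics to [schedule_routine_visits()], applied to the
#' telemedical arm's routine contact rates (the source trial reports higher
#' GP and specialist contact under monitoring).
#'
#' @inheritParams schedule_routine_visits
#' @return A tibble with columns `day` and `kind`.
#' @export
telemedical_routine_visits <- function(params, horizon_days, rng) {
  schedule_routine_visits(params, horizon_days, rng)
}

# Control-cycle days are the last day of each week: 6, 13, 20, ... so a
# horizon of H days contains exactly floor(H / 7) cycles.
is_control_cycle_day <- function(day) {
  day %% 7L == 6L
}
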