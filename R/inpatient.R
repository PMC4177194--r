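# Inpatient care: one admission from arrival to discharge or in-hospital
# death. The ward/ICU split, any individual medical procedures, the length
# of stay and the discharge NYHA transition are all drawn from the
# admitting patient's class-specific parameters; the two arms share this
# block and differ only through those parameters.

#' Construct a patient state
#'
#' @param id Patient identifier.
#' @param nyha NYHA class, integer 1-4.
#' @param arm Care arm.
#' @param status `"outpatient"`, `"hospitalized"` or `"dead"`.
#' @return A list of class `hf_patient`.
#' @export
patient_state <- function(id, nyha, arm = "conventional",
                          status = "outpatient") {
  stopifnot(status %in% c("outpatient", "hospitalized", "dead"))
  out <- list(id = id, nyha = as_nyha(nyha), arm = as_care_arm(arm),
              status = status)
  class(out) <- "hf_patient"
  out
}

#' Simulate one hospital admission
#'
#' Draws, in order: ICU involvement (`icu_admission_prob`), the ICU stay
#' length when involved (`los_icu_median_days`), the ward stay length
#' (`los_ward_median_days`), an individual medical procedure (`imp_prob`,
#' code by `imp_weights`), and in-hospital death
#' (`in_hospital_mortality_prob`). A death truncates the stay at a day drawn
#' uniformly within the sampled length of stay (ICU days are taken to lie at
#' the start of the stay, when severity is highest). Survivors receive a
#' discharge NYHA class via [sample_nyha_transition()].
#'
#' @param patient An [patient_state()]; must be alive.
#' @param params The patient's class-specific [nyha_parameters()].
#' @param rng An [rng_stream()].
#' @param admit_day Simulation day of admission (default 0).
#' @return A list of class `hf_admission` with fields `patient_id`,
#'   `admit_day`, `ward_days`, `icu_days`, `imp_codes`, `died_in_hospital`,
#'   `nyha_at_admit`, `nyha_at_discharge` (`NA` if died) and `discharge_day`
#'   (day of death for in-hospital deaths).
#' @export
run_admission <- function(patient, params, rng, admit_day = 0L) {
  if (patient$status == "dead") {
    stop("cannot admit a dead patient", call. = FALSE)
  }
  icu <- draw_bernoulli(params$icu_admission_prob, rng)
  icu_days <- if (icu) {
    sample_los(params$los_icu_median_days, params$los_log_sigma, rng)
  } else 0L
  ward_days <- sample_los(params$los_ward_median_days, params$los_log_sigma, rng)
  imp_codes <- character(0)
  if (draw_bernoulli(params$imp_prob, rng)) {
    idx <- draw_categorical(params$imp_weights, rng)
    imp_codes <- names(params$imp_weights)[idx]
  }
  died <- draw_bernoulli(params$in_hospital_mortality_prob, rng)
  total <- ward_days + icu_days
  nyha_discharge <- NA_integer_
  if (died) {
    # Death truncates the stay; ICU days (if any) are accrued first.
    death_offset <- max(1L, as.integer(ceiling(stream_next(rng) * total)))
    total <- death_offset
    icu_days <- min(icu_days, total)
    ward_days <- total - icu_days
  } else {
    nyha_discharge <- sample_nyha_transition(
      patient$nyha, params$discharge_transition_probs, rng)
  }
  out <- list(
    patient_id = patient$id,
    admit_day = as.integer(admit_day),
    ward_days = as.integer(ward_days),
    icu_days = as.integer(icu_days),
    imp_codes = imp_codes,
    died_in_hospital = died,
    nyha_at_admit = patient$nyha,
    nyha_at_discharge = nyha_discharge,
    discharge_day = as.integer(admit_day + total)
  )
  class(out) <- "hf_admission"
  out
}

#' Expand an admission into its day-stamped event stream
#'
#' @param record An `hf_admission` from [run_admission()].
#' @return A tibble with columns `day`, `patient_id`, `kind`, `n_days`: one
#'   `ward_stay` row, an `icu_stay` row when intensive care was involved,
#'   one `imp` row per procedure code (code in `detail`), and a terminal
#'   `discharge` or `death` row stamped at the end of the stay.
#' @export
admission_event_stream <- function(record) {
  stopifnot(inherits(record, "hf_admission"))
  rows <- list(
    tibble::tibble(day = record$admit_day, patient_id = record$patient_id,
                   kind = "ward_stay", n_days = record$ward_days,
                   detail = NA_character_)
  )
  if (record$icu_days > 0) {
    rows <- c(rows, list(
      tibble::tibble(day = record$admit_day, patient_id = record$patient_id,
                     kind = "icu_stay", n_days = record$icu_days,
                     detail = NA_character_)))
  }
  for (code in record$imp_codes) {
    rows <- c(rows, list(
      tibble::tibble(day = record$admit_day, patient_id = record$patient_id,
                     kind = "imp", n_days = 0L, detail = code)))
  }
  terminal <- if (record$died_in_hospital) "death" else "discharge"
  rows <- c(rows, list(
    tibble::tibble(day = record$discharge_day, patient_id = record$patient_id,
                   kind = terminal, n_days = 0L, detail = NA_character_)))
  dplyr::bind_rows(rows)
}
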