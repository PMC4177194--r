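# Cost engine: LDF case flat rates with trim-point logic, daily ICU
# supplements, procedure components, outpatient tariffs and the two
# telemonitoring financing variants.
#
# All user-facing amounts are euros. Inside the engine each cost line is an
# integer number of euro cents, so scenario totals are exact sums of their
# parts with no floating-point drift in the accounting.

COST_CATEGORIES <- c("ward", "icu", "imp", "outpatient_standard",
                     "telemed_system")

# Round a euro amount to integer cents (half away from zero).
as_cents <- function(eur) {
  as.integer(round(eur * 100))
}

#' LDF reimbursement for one hospital stay
#'
#' Stays within the trim points earn the case flat rate; each day beyond
#' `trim_max_days` adds the daily supplement; stays shorter than
#' `trim_min_days` earn the reduced flat rate. Both trim boundaries are
#' inclusive. The stay length used here is the total in-hospital time
#' (ward + ICU days); ICU time is additionally reimbursed through
#' [icu_supplement()].
#'
#' @param los_days Total length of stay in days (>= 1).
#' @param ldf An [ldf_group()].
#' @param euro_per_point Point-to-euro conversion factor.
#' @return Reimbursement in euros.
#' @examples
#' ldf_reimbursement(10, ldf_group(), 1)  # 1523
#' @export
ldf_reimbursement <- function(los_days, ldf, euro_per_point) {
  if (los_days < 1) stop("`los_days` must be >= 1", call. = FALSE)
  points <- if (los_days < ldf$trim_min_days) {
    ldf$flat_points * ldf$reduced_flat_fraction
  } else if (los_days <= ldf$trim_max_days) {
    ldf$flat_points
  } else {
    ldf$flat_points + (los_days - ldf$trim_max_days) * ldf$daily_supplement_points
  }
  points * euro_per_point
}

#' Daily ICU supplement for one stay
#'
#' @param icu_days Intensive-care days (>= 0).
#' @param ldf An [ldf_group()].
#' @param euro_per_point Point-to-euro conversion factor.
#' @return Supplement in euros (`icu_days * icu_daily_supplement_points *
#'   euro_per_point`).
#' @export
icu_supplement <- function(icu_days, ldf, euro_per_point) {
  stopifnot(icu_days >= 0)
  icu_days * ldf$icu_daily_supplement_points * euro_per_point
}

#' Procedure-component cost of an admission
#'
#' @param codes Character vector of procedure codes (repeats allowed).
#' @param catalogue Tibble with columns `code`, `points`.
#' @param euro_per_point Point-to-euro conversion factor.
#' @return Total procedure cost in euros.
#' @export
imp_cost <- function(codes, catalogue, euro_per_point) {
  if (length(codes) == 0) return(0)
  idx <- match(codes, catalogue$code)
  if (anyNA(idx)) {
    stop(sprintf("unknown procedure code '%s'", codes[which(is.na(idx))[1]]),
         call. = FALSE)
  }
  sum(catalogue$points[idx]) * euro_per_point
}

#' Tariff for one outpatient event
#'
#' Maps an outpatient or telemedical outcome kind to its tariff. Ambulance
#' visits, emergency transports and medication changes cost 0 when the
#' corresponding scenario toggle is off (as in the packaged reference
#' scenarios). Telemedical doctor visits are tariffed like GP visits; `none`,
#' `intervention` and the admission/death kinds carry no outpatient tariff.
#'
#' @param kind An outcome kind (see [conventional_daily_cycle()] and
#'   [telemedical_control_cycle()]).
#' @param tariffs A [cost_tariffs()].
#' @param toggles Scenario toggles.
#' @return Cost in euros.
#' @export
outpatient_event_cost <- function(kind, tariffs, toggles = list()) {
  on <- function(name) isTRUE(toggles[[name]])
  switch(kind,
    none = 0,
    intervention = 0,
    referral_admission = 0,
    extramural_death = 0,
    death = 0,
    gp_visit = tariffs$gp_visit_eur,
    doctor_visit = tariffs$gp_visit_eur,
    specialist_visit = tariffs$specialist_visit_eur,
    home_visit = tariffs$home_visit_eur,
    ambulance_visit = if (on("ambulance_costs")) tariffs$ambulance_visit_eur else 0,
    medication_change = if (on("medication_costs")) tariffs$medication_event_eur else 0,
    emergency_admission = if (on("transport_costs")) tariffs$emergency_transport_eur else 0,
    stop(sprintf("unknown outpatient event kind '%s'", kind), call. = FALSE)
  )
}

#' System cost lines for the telemonitoring financing variants
#'
#' Variant A emits one line per patient-month at the all-in monthly rate.
#' Variant B emits one acquisition line per patient at month 0, one
#' cohort-level overhead line per month, and one physician-fee line per
#' patient-month.
#'
#' @param financing A [telemed_financing()].
#' @param n_patients Number of monitored patients.
#' @param elapsed_months Whole months elapsed (>= 0).
#' @return A tibble of cost lines with columns `month`, `patient_id`
#'   (`NA` for cohort-level lines), `category` (`"telemed_system"`) and
#'   `amount_eur`.
#' @export
telemed_system_cost <- function(financing, n_patients, elapsed_months) {
  if (is.null(financing)) {
    stop("telemedical arm without a financing scheme", call. = FALSE)
  }
  stopifnot(elapsed_months >= 0, n_patients >= 0)
  months <- seq_len(elapsed_months) - 1L
  rows <- list()
  if (financing$variant == "A") {
    if (elapsed_months > 0 && n_patients > 0) {
      grid <- tidyr::expand_grid(month = months, patient_id = seq_len(n_patients))
      rows <- list(tibble::tibble(
        month = grid$month, patient_id = grid$patient_id,
        category = "telemed_system",
        amount_eur = financing$monthly_rate_per_patient_eur))
    }
  } else {
    if (n_patients > 0) {
      rows <- c(rows, list(tibble::tibble(
        month = 0L, patient_id = seq_len(n_patients),
        category = "telemed_system",
        amount_eur = financing$acquisition_per_system_eur)))
    }
    if (elapsed_months > 0) {
      rows <- c(rows, list(tibble::tibble(
        month = months, patient_id = NA_integer_,
        category = "telemed_system",
        amount_eur = financing$monthly_overhead_eur)))
      if (n_patients > 0) {
        grid <- tidyr::expand_grid(month = months,
                                   patient_id = seq_len(n_patients))
        rows <- c(rows, list(tibble::tibble(
          month = grid$month, patient_id = grid$patient_id,
          category = "telemed_system",
          amount_eur = financing$physician_fee_per_patient_month_eur)))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(month = integer(0), patient_id = integer(0),
                          category = character(0), amount_eur = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Total reimbursement for one admission
#'
#' Sum of the LDF flat rate over the total stay (ward + ICU days, with deaths
#' costed by the days actually accrued), the daily ICU supplement, and any
#' procedure components.
#'
#' @param record An `hf_admission` from [run_admission()].
#' @param ldf The admitting class's [ldf_group()].
#' @param catalogue Procedure catalogue tibble (`code`, `points`).
#' @param euro_per_point Point-to-euro conversion factor.
#' @return Total cost in euros.
#' @examples
#' # a 10-day ward stay within trim points under the default tariffs
#' rec <- structure(list(patient_id = 1L, admit_day = 0L, ward_days = 10L,
#'                       icu_days = 0L, imp_codes = character(0),
#'                       died_in_hospital = FALSE, nyha_at_admit = 2L,
#'                       nyha_at_discharge = 2L, discharge_day = 10L),
#'                  class = "hf_admission")
#' admission_total_cost(rec, ldf_group(),
#'                      tibble::tibble(code = "IMP-A", points = 2500), 1)
#' @export
admission_total_cost <- function(record, ldf, catalogue, euro_per_point) {
  stopifnot(inherits(record, "hf_admission"))
  los <- record$ward_days + record$icu_days
  ldf_reimbursement(los, ldf, euro_per_point) +
    icu_supplement(record$icu_days, ldf, euro_per_point) +
    imp_cost(record$imp_codes, catalogue, euro_per_point)
}
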