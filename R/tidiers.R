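# broom-style tidiers: tidy() returns long daily series, glance() one-row
# scenario summaries.

#' @describeIn run_single Long-format daily series of one run: columns
#'   `day`, `series`, `value`.
#' @param x An `hf_run`.
#' @param ... Unused.
#' @export
tidy.hf_run <- function(x, ...) {
  x$daily |>
    tidyr::pivot_longer(-"day", names_to = "series", values_to = "value")
}

#' @describeIn run_single One-row summary of a run.
#' @export
glance.hf_run <- function(x, ...) {
  last <- x$daily[nrow(x$daily), ]
  tibble::tibble(
    label = x$label,
    arm = x$arm,
    run_index = x$run_index,
    horizon_days = nrow(x$daily),
    n_patients = last$alive + last$dead,
    deaths = last$dead,
    admissions = nrow(x$admissions),
    total_cost_eur = last$cum_total,
    ward_cost_eur = last$cum_ward,
    icu_cost_eur = last$cum_icu,
    imp_cost_eur = last$cum_imp,
    outpatient_cost_eur = last$cum_outpatient_standard,
    telemed_system_cost_eur = last$cum_telemed_system
  )
}

#' @describeIn run_scenario Long-format mean daily series with run-to-run
#'   standard deviation: columns `day`, `series`, `mean`, `sd`.
#' @param x An `hf_scenario_result`.
#' @param ... Unused.
#' @export
tidy.hf_scenario_result <- function(x, ...) {
  m <- x$daily_mean |>
    tidyr::pivot_longer(-"day", names_to = "series", values_to = "mean")
  s <- x$daily_sd |>
    tidyr::pivot_longer(-"day", names_to = "series", values_to = "sd")
  dplyr::left_join(m, s, by = c("day", "series"))
}

#' @describeIn run_scenario One-row summary: mean deaths, mean admissions
#'   per run and mean cost totals by category.
#' @export
glance.hf_scenario_result <- function(x, ...) {
  last <- x$daily_mean[nrow(x$daily_mean), ]
  adm <- if (length(x$runs) > 0) {
    mean(purrr::map_int(x$runs, function(r) nrow(r$admissions)))
  } else NA_real_
  tibble::tibble(
    label = x$label,
    arm = x$arm,
    n_runs = length(x$runs),
    horizon_days = nrow(x$daily_mean),
    n_patients = last$alive + last$dead,
    deaths = last$dead,
    admissions = adm,
    total_cost_eur = last$cum_total,
    ward_cost_eur = last$cum_ward,
    icu_cost_eur = last$cum_icu,
    imp_cost_eur = last$cum_imp,
    outpatient_cost_eur = last$cum_outpatient_standard,
    telemed_system_cost_eur = last$cum_telemed_system
  )
}

#' @describeIn compare_arms Yearly comparison table in long-friendly form.
#' @param x An `hf_comparison`.
#' @param ... Unused.
#' @export
tidy.hf_comparison <- function(x, ...) {
  x$yearly
}

#' @describeIn compare_arms One-row summary with break-even day and deaths.
#' @export
glance.hf_comparison <- function(x, ...) {
  tibble::tibble(
    conv_label = x$labels[["conv"]],
    tm_label = x$labels[["tm"]],
    break_even_day = x$break_even_day,
    deaths_conv = x$deaths[["conv"]],
    deaths_tm = x$deaths[["tm"]],
    year1_pct_of_conventional = x$yearly$pct_of_conventional[1],
    final_cum_pct_of_conventional =
      x$yearly$cum_pct_of_conventional[nrow(x$yearly)]
  )
}
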