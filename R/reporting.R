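# Reporting: arm comparisons normalised to conventional care = 100%,
# break-even detection on cumulative cost curves, mortality and NYHA
# summaries, and one-at-a-time sensitivity sweeps.

#' First day one cumulative cost curve falls to or below another
#'
#' Given two equal-length daily cumulative series (day 0 first), returns the
#' first day `d >= 1` at which `series_b(d) <= series_a(d)` - the break-even
#' day of the initially more expensive concept `b` against comparator `a` -
#' or `NA` if the curves never cross within the horizon.
#'
#' @param series_a,series_b Numeric vectors of cumulative cost, element `t`
#'   being day `t - 1`.
#' @return Integer day, or `NA_integer_`.
#' @export
break_even <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(series_a) < 2) return(NA_integer_)
  hit <- which(series_b[-1] <= series_a[-1])
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

# Per-year cost slices: years are days [0,365), [365,730), ...
.yearly_costs <- function(daily, col = "cum_total") {
  h <- nrow(daily)
  n_years <- ceiling(h / 365)
  purrr::map_dbl(seq_len(n_years), function(y) {
    lo <- (y - 1) * 365
    hi <- min(y * 365, h) - 1
    end <- daily[[col]][hi + 1]
    start <- if (lo == 0) 0 else daily[[col]][lo]
    end - start
  })
}

#' Compare two scenario results arm against arm
#'
#' Computes yearly and cumulative total costs for both results, expresses
#' the second ("telemedical") as a percentage of the first ("conventional"
#' = 100%), detects the break-even day on the mean cumulative total-cost
#' curves and tallies mean deaths per arm.
#'
#' @param conv,tm `hf_scenario_result` objects over the same horizon and
#'   cohort size (conventional first).
#' @return An object of class `hf_comparison`: `yearly` tibble (`year`,
#'   `conv_cost_eur`, `tm_cost_eur`, `pct_of_conventional`,
#'   `cum_pct_of_conventional`), `break_even_day`, `deaths` (named vector),
#'   and `category_totals` tibble.
#' @export
compare_arms <- function(conv, tm) {
  if (nrow(conv$daily_mean) != nrow(tm$daily_mean)) {
    stop("results cover different horizons", call. = FALSE)
  }
  n_conv <- conv$daily_mean$alive[1] + conv$daily_mean$dead[1]
  n_tm <- tm$daily_mean$alive[1] + tm$daily_mean$dead[1]
  if (n_conv != n_tm) {
    stop("results use different cohort sizes", call. = FALSE)
  }
  yc <- .yearly_costs(conv$daily_mean)
  yt <- .yearly_costs(tm$daily_mean)
  yearly <- tibble::tibble(
    year = seq_along(yc),
    conv_cost_eur = yc,
    tm_cost_eur = yt,
    pct_of_conventional = 100 * yt / yc,
    cum_pct_of_conventional = 100 * cumsum(yt) / cumsum(yc)
  )
  be <- break_even(conv$daily_mean$cum_total, tm$daily_mean$cum_total)
  cat_cols <- c("cum_ward", "cum_icu", "cum_imp", "cum_outpatient_standard",
                "cum_telemed_system")
  last <- function(res) {
    unlist(res$daily_mean[nrow(res$daily_mean), cat_cols])
  }
  category_totals <- tibble::tibble(
    category = sub("^cum_", "", cat_cols),
    conv_cost_eur = last(conv),
    tm_cost_eur = last(tm)
  )
  out <- list(
    labels = c(conv = conv$label, tm = tm$label),
    yearly = yearly,
    break_even_day = be,
    deaths = c(conv = conv$daily_mean$dead[nrow(conv$daily_mean)],
               tm = tm$daily_mean$dead[nrow(tm$daily_mean)]),
    category_totals = category_totals
  )
  class(out) <- "hf_comparison"
  out
}

#' @export
print.hf_comparison <- function(x, ...) {
  cat(sprintf("<hf_comparison> %s vs %s (conventional = 100%%)\n",
              x$labels["conv"], x$labels["tm"]))
  print(x$yearly)
  be <- if (is.na(x$break_even_day)) "not reached within the horizon" else
    sprintf("day %d", x$break_even_day)
  cat(sprintf("break-even: %s; mean deaths %.1f vs %.1f\n",
              be, x$deaths["conv"], x$deaths["tm"]))
  invisible(x)
}

#' Mortality summary of a scenario result
#'
#' Deaths per NYHA class (at death) and cause, averaged over runs and
#' cross-checked against the alive/dead daily series.
#'
#' @param result An `hf_scenario_result` with per-run logs.
#' @return A tibble with columns `cause` (`in_hospital` / `extramural`),
#'   `nyha`, `deaths_total` (across runs) and `deaths_per_run`.
#' @export
mortality_summary <- function(result) {
  n_runs <- length(result$runs)
  ev <- dplyr::bind_rows(purrr::map(result$runs, "events"))
  deaths <- dplyr::filter(ev, .data$kind %in% c("death_in_hospital",
                                                "extramural_death"))
  grid <- tidyr::expand_grid(
    cause = c("in_hospital", "extramural"), nyha = 1:4)
  if (nrow(deaths) > 0) {
    counts <- deaths |>
      dplyr::mutate(cause = ifelse(.data$kind == "death_in_hospital",
                                   "in_hospital", "extramural")) |>
      dplyr::count(.data$cause, .data$nyha, name = "deaths_total")
  } else {
    counts <- tibble::tibble(cause = character(), nyha = integer(),
                             deaths_total = integer())
  }
  grid |>
    dplyr::left_join(counts, by = c("cause", "nyha")) |>
    dplyr::mutate(deaths_total = dplyr::coalesce(.data$deaths_total, 0L),
                  deaths_per_run = .data$deaths_total / n_runs)
}

#' Daily NYHA class distribution of a scenario result
#'
#' @param result An `hf_scenario_result` (or `hf_run`).
#' @return A tibble with columns `day`, `nyha`, `count` (mean over runs for
#'   scenario results); counts sum to the number of patients alive that day.
#' @export
nyha_timeseries <- function(result) {
  daily <- if (inherits(result, "hf_run")) result$daily else result$daily_mean
  daily |>
    dplyr::select("day", dplyr::starts_with("nyha_")) |>
    tidyr::pivot_longer(dplyr::starts_with("nyha_"),
                        names_to = "nyha", names_prefix = "nyha_",
                        values_to = "count") |>
    dplyr::mutate(nyha = as.integer(.data$nyha))
}

# Set a scenario field addressed by a dot-separated path, e.g.
# "tariffs.gp_visit_eur" or "nyha_params.2.imp_prob"; an unindexed
# "nyha_params.<field>" or "ldf.<field>" applies to all four classes.
set_config_value <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  per_class <- parts[1] %in% c("nyha_params", "ldf") &&
    length(parts) >= 2 && is.na(suppressWarnings(as.integer(parts[2])))
  idx <- purrr::map(parts, function(p) {
    k <- suppressWarnings(as.integer(p))
    if (is.na(k)) p else k
  })
  if (per_class) {
    for (k in 1:4) {
      full <- c(idx[1], list(k), idx[-1])
      if (is.null(purrr::pluck(cfg, !!!full))) {
        stop(sprintf("config path '%s' does not resolve", path), call. = FALSE)
      }
      purrr::pluck(cfg, !!!full) <- value
    }
  } else {
    if (is.null(purrr::pluck(cfg, !!!idx))) {
      stop(sprintf("config path '%s' does not resolve", path), call. = FALSE)
    }
    purrr::pluck(cfg, !!!idx) <- value
  }
  cfg
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs a full scenario for each value of one configuration parameter,
#' everything else (including seeds) held fixed, and tabulates the requested
#' summary outputs.
#'
#' @param base An `hf_scenario` to perturb.
#' @param parameter Dot-separated path into the configuration, e.g.
#'   `"tariffs.gp_visit_eur"`, `"financing.monthly_rate_per_patient_eur"`,
#'   `"nyha_params.in_hospital_mortality_prob"` (unindexed per-class paths
#'   apply to all four classes; use `"nyha_params.2.<field>"` for one class).
#' @param values Vector of values to sweep over.
#' @param outputs Character vector of [glance()] column names to report.
#' @return A tibble with one row per value: `parameter`, `value` and the
#'   requested outputs.
#' @export
sensitivity_sweep <- function(base, parameter, values,
                              outputs = c("total_cost_eur", "deaths")) {
  purrr::map_dfr(values, function(v) {
    cfg <- set_config_value(base, parameter, v)
    viol <- validate_scenario(cfg)
    if (nrow(viol) > 0) {
      stop(sprintf("sweep value %s for '%s' makes the scenario invalid (%s)",
                   format(v), parameter, viol$field[1]), call. = FALSE)
    }
    g <- glance(run_scenario(cfg))
    bad <- setdiff(outputs, names(g))
    if (length(bad) > 0) {
      stop(sprintf("unknown output field '%s'", bad[1]), call. = FALSE)
    }
    dplyr::bind_cols(tibble::tibble(parameter = parameter, value = v),
                     g[outputs])
  })
}
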