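# ggplot2 methods for the result types.

#' Plot cumulative costs of a scenario result
#'
#' Mean cumulative cost over time, one line per cost category plus the
#' total; the shaded band on the total is +/- one run-to-run standard
#' deviation.
#'
#' @param object An `hf_scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hf_scenario_result <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(grepl("^cum_", .data$series)) |>
    dplyr::mutate(series = sub("^cum_", "", .data$series))
  ggplot2::ggplot(td, ggplot2::aes(.data$day, .data$mean,
                                   colour = .data$series)) +
    ggplot2::geom_ribbon(
      data = dplyr::filter(td, .data$series == "total"),
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      fill = "grey80", colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "cumulative cost (EUR)", colour = "category",
                  title = sprintf("Scenario '%s' (%s arm)",
                                  object$label, object$arm)) +
    ggplot2::theme_minimal()
}

#' Plot an arm comparison as normalised yearly bars
#'
#' Yearly total costs of the telemedical arm expressed as a percentage of
#' conventional care (= 100%, dashed line).
#'
#' @param object An `hf_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hf_comparison <- function(object, ...) {
  ggplot2::ggplot(object$yearly,
                  ggplot2::aes(factor(.data$year),
                               .data$pct_of_conventional)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = "year", y = "% of conventional care",
                  title = sprintf("%s vs %s", object$labels[["tm"]],
                                  object$labels[["conv"]])) +
    ggplot2::theme_minimal()
}

#' Plot the NYHA class distribution over time
#'
#' @param result An `hf_scenario_result` or `hf_run`.
#' @return A ggplot object (stacked area of per-class patient counts).
#' @export
plot_nyha_timeseries <- function(result) {
  ggplot2::ggplot(nyha_timeseries(result),
                  ggplot2::aes(.data$day, .data$count,
                               fill = factor(.data$nyha))) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "day", y = "patients alive", fill = "NYHA class") +
    ggplot2::theme_minimal()
}
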