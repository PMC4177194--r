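# Reporting: break-even detection, arm comparison, mortality and NYHA
# summaries, sensitivity sweeps, command-line front end.

test_that("break_even matches a brute-force scan on constructed and random series", {
  t <- 0:364
  expect_identical(break_even(2 * t, t + 100), 100L)   # closed-form crossing
  expect_true(is.na(break_even(t, t + 1)))             # never crosses
  expect_identical(break_even(t, t), 1L)               # equal series convention

  brute <- function(a, b) {
    for (d in seq_along(a)[-1]) if (b[d] <= a[d]) return(d - 1L)
    NA_integer_
  }
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    a <- cumsum(stats::runif(n, 0, 2))
    b <- stats::runif(1, 0, 5) + cumsum(stats::runif(n, 0, 2))
    expect_identical(break_even(a, b), brute(a, b))
  }
  expect_error(break_even(1:5, 1:6), "equal length")
})

test_that("comparing an arm against itself gives 100% and swapping inverts", {
  cfg <- small_cfg(n_patients = 10, horizon_days = 400, n_runs = 2,
                   params = params_with(period_hospitalization_prob = 0.4,
                                        worsening_prob_per_day = NULL,
                                        los_log_sigma = 0.5,
                                        gp_visits_per_year = 2))
  res <- run_scenario(cfg)
  self <- compare_arms(res, res)
  expect_true(all(abs(self$yearly$pct_of_conventional - 100) < 1e-9))
  expect_identical(unname(self$deaths["conv"]), unname(self$deaths["tm"]))

  cfg2 <- cfg
  cfg2$seed <- 11L
  res2 <- run_scenario(cfg2)
  fwd <- compare_arms(res, res2)
  rev <- compare_arms(res2, res)
  expect_equal(rev$yearly$pct_of_conventional,
               100^2 / fwd$yearly$pct_of_conventional)

  short <- run_scenario(small_cfg(n_patients = 10, horizon_days = 100))
  expect_error(compare_arms(res, short), "horizons")
})

test_that("mortality summaries agree with the daily series and event logs", {
  quiet <- run_scenario(small_cfg(n_patients = 5, horizon_days = 50))
  ms0 <- mortality_summary(quiet)
  expect_true(all(ms0$deaths_total == 0))

  lethal <- run_scenario(small_cfg(
    n_patients = 1, horizon_days = 40, n_runs = 2,
    params = params_with(worsening_prob_per_day = 1,
                         emergency_prob_given_worsening = 1,
                         in_hospital_mortality_prob = 1,
                         los_ward_median_days = 5)))
  ms <- mortality_summary(lethal)
  expect_identical(sum(ms$deaths_total[ms$cause == "in_hospital"]), 2L)
  expect_identical(sum(ms$deaths_total[ms$cause == "extramural"]), 0L)
  expect_equal(sum(ms$deaths_per_run),
               lethal$daily_mean$dead[nrow(lethal$daily_mean)])
})

test_that("the NYHA time series partitions the living cohort", {
  cfg <- small_cfg(n_patients = 12, horizon_days = 150, n_runs = 2,
                   params = params_with(period_hospitalization_prob = 0.5,
                                        worsening_prob_per_day = NULL,
                                        los_log_sigma = 0.5,
                                        in_hospital_mortality_prob = 0.2))
  res <- run_scenario(cfg)
  ts <- nyha_timeseries(res)
  sums <- ts |>
    dplyr::summarise(total = sum(.data$count), .by = "day")
  expect_equal(sums$total, res$daily_mean$alive)
  expect_identical(nrow(ts), nrow(res$daily_mean) * 4L)
})

test_that("sensitivity sweeps rerun the scenario with one field changed", {
  cfg <- small_cfg(arm = "telemedical", n_patients = 3, horizon_days = 70,
                   n_runs = 1)
  tab <- sensitivity_sweep(cfg, "financing.monthly_rate_per_patient_eur",
                           c(0, 50),
                           outputs = c("telemed_system_cost_eur", "deaths"))
  expect_equal(tab$telemed_system_cost_eur[1], 0)
  expect_equal(tab$telemed_system_cost_eur[2],
               tab$telemed_system_cost_eur[1] + 50 * 3 *
                 sum(vapply(0:69, telehf:::is_month_start, logical(1))))

  # mortality extremes: no deaths vs one death per admission
  cfg2 <- small_cfg(n_patients = 4, horizon_days = 80, n_runs = 1,
                    params = params_with(period_hospitalization_prob = 0.6,
                                         worsening_prob_per_day = NULL,
                                         los_log_sigma = 0.5))
  tab2 <- sensitivity_sweep(cfg2, "nyha_params.in_hospital_mortality_prob",
                            c(0, 1), outputs = c("deaths", "admissions"))
  expect_equal(tab2$deaths[1], 0)
  expect_equal(tab2$deaths[2], tab2$admissions[2])  # every admission is fatal

  expect_error(sensitivity_sweep(cfg, "no.such.path", 1), "resolve")
})

test_that("the command-line front end wires the subcommands together", {
  out_fix <- withr::local_tempdir()
  expect_identical(suppressMessages(cli_main(c("fixtures", "--out", out_fix))),
                   0L)
  expect_identical(sort(list.files(out_fix)),
                   c("scenario_conventional.yaml", "scenario_tm_a.yaml",
                     "scenario_tm_b.yaml"))

  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(small_cfg(n_patients = 3, horizon_days = 40, n_runs = 1),
                 cfg_file)
  res_dir <- withr::local_tempdir()
  expect_identical(
    suppressMessages(cli_main(c("run", "--config", cfg_file,
                                "--out", res_dir, "--quiet"))), 0L)
  expect_true(file.exists(file.path(res_dir, "summary.json")))
  summary <- jsonlite::read_json(file.path(res_dir, "summary.json"))
  expect_true(all(c("deaths", "total_cost_eur") %in% names(summary)))

  # compare two serialised runs of the same scenario
  cmp_csv <- withr::local_tempfile(fileext = ".csv")
  invisible(utils::capture.output(
    status <- suppressMessages(
      cli_main(c("compare", "--conv", res_dir, "--tm", res_dir,
                 "--out", cmp_csv, "--quiet")))))
  expect_identical(status, 0L)
  expect_true(file.exists(cmp_csv))

  expect_identical(suppressMessages(cli_main(c("run", "--config"))), 1L)
  expect_identical(suppressMessages(cli_main("nonsense")), 1L)
  expect_identical(cli_main(character(0)), 1L)
})
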