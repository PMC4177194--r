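# Simulation engine: conservation, monotonicity, determinism, substream
# stability, accounting identities, serialisation.

test_that("patient counts are conserved and cumulative costs never decrease", {
  cfg <- small_cfg(n_patients = 20, horizon_days = 200, n_runs = 2,
                   params = params_with(period_hospitalization_prob = 0.4,
                                        worsening_prob_per_day = NULL,
                                        los_log_sigma = 0.5,
                                        icu_admission_prob = 0.126,
                                        imp_prob = 0.05,
                                        in_hospital_mortality_prob = 0.2,
                                        gp_visits_per_year = 2))
  res <- run_scenario(cfg)
  for (run in res$runs) {
    d <- run$daily
    expect_true(all(d$alive + d$dead == 20))
    expect_true(all(d$nyha_1 + d$nyha_2 + d$nyha_3 + d$nyha_4 == d$alive))
    for (col in grep("^cum_", names(d), value = TRUE)) {
      expect_true(all(diff(d[[col]]) >= 0), label = paste(col, "monotone"))
    }
    expect_true(all(run$events$day >= 0 & run$events$day < 200))
  }
})

test_that("runs are bit-identical under a fixed seed and stable under cohort growth", {
  cfg <- small_cfg(n_patients = 10, horizon_days = 150, n_runs = 1,
                   params = params_with(period_hospitalization_prob = 0.4,
                                        worsening_prob_per_day = NULL,
                                        los_log_sigma = 0.5,
                                        in_hospital_mortality_prob = 0.1,
                                        gp_visits_per_year = 2))
  r1 <- run_single(cfg, 1)
  r2 <- run_single(cfg, 1)
  expect_identical(r1$daily, r2$daily)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$cost_lines, r2$cost_lines)
  expect_false(identical(r1$events, run_single(cfg, 2)$events))

  # adding patients leaves the original patients' trajectories untouched
  cfg15 <- cfg
  cfg15$n_patients <- 15L
  r15 <- run_single(cfg15, 1)
  keep <- function(r) dplyr::filter(r$events, .data$patient_id <= 10)
  expect_identical(keep(r15), keep(r1))
})

test_that("a silent cohort accrues only telemonitoring system fees", {
  cfg <- small_cfg(arm = "telemedical", n_patients = 4, horizon_days = 100,
                   n_runs = 2)
  res <- run_scenario(cfg)
  n_months <- sum(vapply(seq_len(100) - 1L, telehf:::is_month_start,
                         logical(1)))
  for (run in res$runs) {
    expect_identical(unique(run$cost_lines$category), "telemed_system")
    last <- run$daily[nrow(run$daily), ]
    expect_equal(last$cum_total, 4 * 100 * n_months)
    expect_equal(last$dead, 0)
  }
  # zero run-to-run variance in the degenerate configuration
  expect_true(all(res$daily_sd$cum_total == 0))

  # every patient initialised to the configured class
  expect_true(all(res$runs[[1]]$daily$nyha_2 == res$runs[[1]]$daily$alive))
})

test_that("a forced-path patient dies after exactly one admission", {
  cfg <- small_cfg(n_patients = 1, horizon_days = 40, n_runs = 1,
                   params = params_with(worsening_prob_per_day = 1,
                                        emergency_prob_given_worsening = 1,
                                        in_hospital_mortality_prob = 1,
                                        los_ward_median_days = 5))
  run <- run_single(cfg, 1)
  expect_identical(nrow(run$admissions), 1L)
  expect_identical(sum(run$events$kind == "emergency_admission"), 1L)
  expect_identical(sum(run$events$kind == "death_in_hospital"), 1L)
  expect_true(all(run$daily$alive + run$daily$dead == 1))
  expect_equal(run$daily$dead[nrow(run$daily)], 1)
  # death is absorbing: nothing happens after the death day
  death_day <- run$events$day[run$events$kind == "death_in_hospital"]
  expect_true(all(run$events$day <= death_day))
})

test_that("scenario totals equal the cent-exact sum of their cost lines", {
  cfg <- small_cfg(arm = "telemedical", n_patients = 8, horizon_days = 120,
                   n_runs = 2,
                   params = params_with(period_hospitalization_prob = 0.4,
                                        tm_alarm_prob_per_cycle = NULL,
                                        los_log_sigma = 0.5,
                                        icu_admission_prob = 0.3,
                                        imp_prob = 0.2,
                                        in_hospital_mortality_prob = 0.1,
                                        gp_visits_per_year = 3))
  res <- run_scenario(cfg)
  for (run in res$runs) {
    last <- run$daily[nrow(run$daily), ]
    # category subtotals from the raw lines, in integer cents
    by_cat <- tapply(run$cost_lines$amount_cents, run$cost_lines$category, sum)
    expect_identical(sum(run$cost_lines$amount_cents),
                     as.integer(round(last$cum_total * 100)))
    for (cat in names(by_cat)) {
      col <- paste0("cum_",
                    ifelse(cat == "outpatient_standard",
                           "outpatient_standard", cat))
      expect_identical(as.integer(by_cat[[cat]]),
                       as.integer(round(last[[col]] * 100)))
    }
  }
})

test_that("the n_runs = 1 mean equals the single run and results serialise", {
  cfg <- small_cfg(n_patients = 3, horizon_days = 50, n_runs = 1,
                   params = params_with(period_hospitalization_prob = 0.3,
                                        worsening_prob_per_day = NULL,
                                        gp_visits_per_year = 2))
  res <- run_scenario(cfg)
  expect_equal(as.data.frame(res$daily_mean),
               as.data.frame(res$runs[[1]]$daily))

  dir <- withr::local_tempdir()
  write_scenario_result(res, dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- read_scenario_result(dir)
  expect_equal(as.data.frame(back$daily_mean), as.data.frame(res$daily_mean),
               tolerance = 1e-8)
  expect_identical(back$arm, res$arm)
})
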