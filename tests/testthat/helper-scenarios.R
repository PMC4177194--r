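# Shared fixture builders: all scenarios used by the unit tests are built in
# code, starting from a quiet baseline and overriding only what a test needs.

# Parameter bundle with overrides applied after construction (so defaults
# that nyha_parameters() computes lazily, like calibration, stay NULL).
params_with <- function(..., base = NULL) {
  p <- base %||% nyha_parameters(
    period_hospitalization_prob = 0,
    worsening_prob_per_day = 0,
    tm_alarm_prob_per_cycle = 0,
    los_log_sigma = 0
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Small scenario for engine tests: quiet by default (no events, no deaths).
small_cfg <- function(arm = "conventional", n_patients = 5, horizon_days = 60,
                      n_runs = 2, seed = 7, params = params_with(),
                      financing = NULL, toggles = list(), ...) {
  if (arm == "telemedical" && is.null(financing)) {
    financing <- telemed_financing("A", monthly_rate_per_patient_eur = 100)
  }
  scenario_config(
    arm = arm,
    n_patients = n_patients,
    nyha_distribution = c(0, 1, 0, 0),
    horizon_days = horizon_days,
    n_runs = n_runs,
    seed = seed,
    nyha_params = params,
    financing = financing,
    toggles = toggles,
    ...
  )
}

# 3-sigma binomial band check.
expect_binomial <- function(observed, p, n, label = "frequency") {
  band <- 3 * sqrt(p * (1 - p) / n)
  expect_true(abs(observed - p) <= band,
              label = sprintf("%s %.5f within %.5f +/- %.5f",
                              label, observed, p, band))
}
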