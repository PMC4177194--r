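# Cost engine: trim-point logic, supplements, procedure components,
# outpatient tariffs, financing variants, and the algebraic properties
# (monotonicity, homogeneity, additivity of the admission total).

ldf_fix <- ldf_group()  # packaged defaults: 1523 points, trims 4/12, ICU 1248/day

test_that("LDF reimbursement follows the trim-point rules", {
  expect_equal(ldf_reimbursement(10, ldf_fix, 1), 1523)
  expect_equal(ldf_reimbursement(4, ldf_fix, 1), 1523)   # lower trim inclusive
  expect_equal(ldf_reimbursement(12, ldf_fix, 1), 1523)  # upper trim inclusive
  expect_equal(ldf_reimbursement(14, ldf_fix, 1), 1523 + 2 * 100)
  expect_equal(ldf_reimbursement(3, ldf_fix, 1), 1523 * 0.5)
  expect_error(ldf_reimbursement(0, ldf_fix, 1), ">= 1")

  # non-decreasing in length of stay
  fees <- vapply(1:30, ldf_reimbursement, numeric(1), ldf = ldf_fix,
                 euro_per_point = 1)
  expect_true(all(diff(fees) >= 0))
})

test_that("ICU supplements and procedure components are linear in their inputs", {
  expect_equal(icu_supplement(0, ldf_fix, 1), 0)
  expect_equal(icu_supplement(2, ldf_fix, 1), 2496)
  expect_equal(icu_supplement(3, ldf_fix, 1), 3744)

  cat <- tibble::tibble(code = c("X1", "X2"), points = c(5000, 120))
  expect_equal(imp_cost(character(0), cat, 1), 0)
  expect_equal(imp_cost("X1", cat, 1), 5000)
  expect_equal(imp_cost(c("X1", "X1"), cat, 1), 10000)
  expect_equal(imp_cost(c("X1", "X2"), cat, 1), 5120)
  expect_error(imp_cost("X9", cat, 1), "unknown procedure code")
})

test_that("outpatient tariffs map kinds and honour the exclusion toggles", {
  tr <- cost_tariffs()
  off <- list()
  on <- list(ambulance_costs = TRUE, medication_costs = TRUE,
             transport_costs = TRUE)
  expect_equal(outpatient_event_cost("gp_visit", tr, off), 25)
  expect_equal(outpatient_event_cost("doctor_visit", tr, off), 25)
  expect_equal(outpatient_event_cost("specialist_visit", tr, off), 31)
  expect_equal(outpatient_event_cost("home_visit", tr, off), 45)
  expect_equal(outpatient_event_cost("none", tr, off), 0)
  expect_equal(outpatient_event_cost("intervention", tr, off), 0)
  expect_equal(outpatient_event_cost("ambulance_visit", tr, off), 0)
  expect_equal(outpatient_event_cost("ambulance_visit", tr, on), 40)
  expect_equal(outpatient_event_cost("medication_change", tr, off), 0)
  expect_equal(outpatient_event_cost("medication_change", tr, on), 30)
  expect_equal(outpatient_event_cost("emergency_admission", tr, off), 0)
  expect_equal(outpatient_event_cost("emergency_admission", tr, on), 150)
  expect_error(outpatient_event_cost("teleportation", tr, off), "unknown")
})

test_that("financing variants produce the documented per-month cost lines", {
  fa <- telemed_financing("A", monthly_rate_per_patient_eur = 100)
  expect_equal(sum(telemed_system_cost(fa, 1, 1)$amount_eur), 100)
  expect_equal(sum(telemed_system_cost(fa, 1, 36)$amount_eur), 3600)
  expect_equal(sum(telemed_system_cost(fa, 1, 0)$amount_eur), 0)

  fb <- telemed_financing("B")
  lines <- telemed_system_cost(fb, 100, 36)
  expect_equal(sum(lines$amount_eur), 100 * 1000 + 36 * 500 + 36 * 100 * 40)
  # overhead lines are cohort-level, acquisition and fees per patient
  expect_identical(sum(is.na(lines$patient_id)), 36L)
  expect_error(telemed_system_cost(NULL, 10, 12), "financing")
})

test_that("admission totals compose the three inpatient components", {
  cat <- tibble::tibble(code = "IMP-A", points = 2500)
  mk <- function(ward, icu, codes = character(0)) {
    structure(list(patient_id = 1L, admit_day = 0L, ward_days = ward,
                   icu_days = icu, imp_codes = codes,
                   died_in_hospital = FALSE, nyha_at_admit = 2L,
                   nyha_at_discharge = 2L, discharge_day = ward + icu),
              class = "hf_admission")
  }
  expect_equal(admission_total_cost(mk(10L, 0L), ldf_fix, cat, 1), 1523)
  expect_equal(admission_total_cost(mk(8L, 2L), ldf_fix, cat, 1), 1523 + 2496)
  expect_equal(admission_total_cost(mk(8L, 2L, "IMP-A"), ldf_fix, cat, 1),
               1523 + 2496 + 2500)

  # homogeneity: doubling the euro-per-point factor doubles every amount
  for (rec in list(mk(10L, 0L), mk(8L, 2L, "IMP-A"), mk(2L, 0L), mk(14L, 3L))) {
    expect_equal(admission_total_cost(rec, ldf_fix, cat, 2),
                 2 * admission_total_cost(rec, ldf_fix, cat, 1))
  }

  # zero point scores silence every inpatient amount
  ldf0 <- ldf_group(flat_points = 1e-9, daily_supplement_points = 0,
                    icu_daily_supplement_points = 0)
  expect_lt(admission_total_cost(mk(14L, 3L), ldf0, cat, 1), 1e-6)
})
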