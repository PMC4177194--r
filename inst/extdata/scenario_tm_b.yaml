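# Reference scenario: telemedical care, financing variant B (cost
# components split out: 1000 EUR acquisition per system, 500 EUR monthly
# cohort overhead, 40 EUR per patient per month physician fee).
#
# Published inputs for the telemedical arm: median ward stay 6.5 days,
# hospitalization 20.37 % per 6-month reference period, GP visits 2.84 and
# specialist visits 0.46 per patient-year; ICU involvement, in-hospital
# mortality, median ICU stay and all tariffs as in the conventional file.
# Keys marked "assumption" are not published; see the methods vignette.
#
# tm_alarm_prob_per_cycle is omitted on purpose: it is calibrated at load
# time so the weekly admission hazard reproduces the 20.37 % per-period
# hospitalization probability under the cascade assumptions below.
schema_version: 1
label: tm_b
arm: telemedical
n_patients: 100
horizon_days: 1095
n_runs: 10
seed: 42
reference_period_days: 182
nyha_distribution: [0.0, 0.61, 0.37, 0.02]
toggles:
  ambulance_costs: false
  medication_costs: false
  transport_costs: false
  extramural_mortality: false
nyha_params:
  shared:
    period_hospitalization_prob: 0.2037
    emergency_prob_given_worsening: 0.10     # assumption
    medication_change_prob: 0.20             # assumption (unused branch in this arm)
    provider_choice_probs:                   # assumption (unused branch in this arm)
      doctor: 0.40
      specialist: 0.25
      ambulance: 0.15
    improvement_prob_after_contact: 0.60     # assumption
    hospitalization_prob_no_improvement: 0.50 # assumption
    extramural_mortality_prob: 0.02          # assumption (toggled off here)
    gp_visits_per_year: 2.84
    specialist_visits_per_year: 0.46
    icu_admission_prob: 0.126
    imp_prob: 0.05                           # assumption
    imp_weights:                             # assumption
      IMP-A: 0.7
      IMP-B: 0.3
    los_ward_median_days: 6.5
    los_icu_median_days: 2
    los_log_sigma: 0.5                       # assumption (medians only published)
    in_hospital_mortality_prob: 0.071
    discharge_transition_probs:              # assumption
      improve: 0.40
      stay: 0.45
      worsen: 0.15
    tm_intervention_success_prob: 0.70       # assumption
    tm_facetoface_adaptation_prob: 0.70      # assumption
    tm_contact_choice_probs:                 # assumption
      home_visit: 0.40
      doctor_visit: 0.40
      hospitalization: 0.20
tariffs:
  gp_visit_eur: 25
  specialist_visit_eur: 31
  ambulance_visit_eur: 40                    # assumption (excluded by toggle)
  home_visit_eur: 45                         # assumption
  emergency_transport_eur: 150               # assumption (excluded by toggle)
  medication_event_eur: 30                   # assumption (excluded by toggle)
  euro_per_ldf_point: 1.0
ldf:
  flat_points: 1523
  trim_min_days: 4
  trim_max_days: 12
  daily_supplement_points: 100               # assumption
  reduced_flat_fraction: 0.5                 # assumption
  icu_daily_supplement_points: 1248
imp_catalogue:
  - code: IMP-A
    points: 2500                             # assumption
  - code: IMP-B
    points: 5000                             # assumption
financing:
  variant: B
  acquisition_per_system_eur: 1000
  monthly_overhead_eur: 500
  physician_fee_per_patient_month_eur: 40
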