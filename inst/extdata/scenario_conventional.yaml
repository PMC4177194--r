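# Reference scenario: conventional care of a 100-patient heart-failure
# cohort over three years, averaged over 10 runs.
#
# Published inputs: median ward stay 10 days, median ICU stay 2 days,
# hospitalization 32.08 % per 6-month reference period, GP visits 1.42 and
# specialist visits 0.30 per patient-year, ICU involvement 12.6 %,
# in-hospital mortality 7.1 %; GP visit 25 EUR, specialist visit 31 EUR,
# in-hospital flat rate 1523 EUR (trim points 4-12 days), ICU supplement
# 1248 EUR/day (2496 EUR for a median 2-day stay).
# Keys marked "assumption" are not published for this model; see the
# methods vignette for how each default was chosen.
#
# worsening_prob_per_day is omitted on purpose: it is calibrated at load
# time so the daily admission hazard reproduces the 32.08 % per-period
# hospitalization probability under the branch assumptions below.
schema_version: 1
label: conventional
arm: conventional
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
    period_hospitalization_prob: 0.3208
    emergency_prob_given_worsening: 0.10     # assumption
    medication_change_prob: 0.20             # assumption
    provider_choice_probs:                   # assumption; sums with the above to 1
      doctor: 0.40
      specialist: 0.25
      ambulance: 0.15
    improvement_prob_after_contact: 0.60     # assumption
    hospitalization_prob_no_improvement: 0.50 # assumption
    extramural_mortality_prob: 0.02          # assumption (toggled off here)
    gp_visits_per_year: 1.42
    specialist_visits_per_year: 0.30
    icu_admission_prob: 0.126
    imp_prob: 0.05                           # assumption
    imp_weights:                             # assumption
      IMP-A: 0.7
      IMP-B: 0.3
    los_ward_median_days: 10
    los_icu_median_days: 2
    los_log_sigma: 0.5                       # assumption (medians only published)
    in_hospital_mortality_prob: 0.071
    discharge_transition_probs:              # assumption
      improve: 0.40
      stay: 0.45
      worsen: 0.15
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
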