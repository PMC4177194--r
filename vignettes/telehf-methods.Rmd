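---
title: "Model, assumptions and numerical choices in telehf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, assumptions and numerical choices in telehf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telehf)
```

`telehf` simulates a cohort of chronic heart-failure patients day by day
through two care concepts — conventional outpatient care and telemedical
home monitoring — and prices every event with an Austrian DRG-style (LDF)
cost engine. This vignette documents the model itself, the parameters that
matter, what the packaged reference scenarios assume, and the numerical and
design choices a user should know before trusting (or overriding) the
defaults.

## Model structure

Each patient carries a NYHA functional class (1–4), a status (outpatient,
hospitalized, dead) and a care arm. Time advances in whole days over a
configurable horizon; death is absorbing and stops all cost accrual from the
next day.

**Conventional outpatient pathway (daily).** A worsening occurs with
probability `worsening_prob_per_day`. It either escalates immediately to an
emergency admission (`emergency_prob_given_worsening`) or resolves into one
of four branches — medication change without personal contact, GP visit,
specialist visit, ambulance visit — whose probabilities sum to one. After
the contact, improvement ends the cycle
(`improvement_prob_after_contact`); otherwise the patient may die
extramurally (only when that toggle is on), be referred to hospital
(`hospitalization_prob_no_improvement`), or carry over with the contact as
the day's outcome. The whole chain resolves within one day: the flowchart's
improvement loop has no stated iteration limit, and a per-day resolution is
the reading consistent with a one-day time step.

**Telemedical outpatient pathway (weekly).** Daily data transmission is
cost-free bookkeeping; the branching happens in the weekly control cycle
(days 6, 13, 20, …, so a horizon of `H` days holds exactly `floor(H/7)`
cycles). An alarm (`tm_alarm_prob_per_cycle`) escalates to emergency, or a
remote intervention is attempted (`tm_intervention_success_prob`); on
failure a face-to-face contact is drawn (home visit / doctor visit / direct
hospitalization), followed by an adaptation attempt
(`tm_facetoface_adaptation_prob`) and, on failure, death or referral as in
the conventional arm. The NYHA class is updated after alarm-raising cycles
only; alarm-free weeks leave it untouched. The inter-arm structure of
admissions is identical — the arms differ only through parameter values.

**Inpatient block (shared).** An admission draws ICU involvement
(`icu_admission_prob`), lengths of stay for ICU and ward, an individual
medical procedure (`imp_prob`, code by `imp_weights`), in-hospital death
(`in_hospital_mortality_prob`) and, for survivors, a one-step NYHA
transition (`discharge_transition_probs`, clamped to 1–4). Discharged
patients re-enter outpatient circulation the day after discharge.

## Calibration to per-period probabilities

Published hospitalization inputs are probabilities per reference period
(32.08 % conventional, 20.37 % telemedical, per 182 days — the 6-month
follow-up of the source telemonitoring trial). These convert to a daily
hazard by

```
h = 1 − (1 − p)^(1 / T)
```

(`daily_hazard_from_period_prob()`). The pathway trigger probabilities are
then solved so that the *pathway's* admission hazard equals `h`: for the
conventional arm `w · P(admission | worsening) = h`, where
`P(admission | worsening) = e + (1−e)(1−i)(1−m)r` is enumerated from the
branch probabilities (emergency `e`, improvement `i`, extramural mortality
`m` when toggled, referral `r`); analogously per weekly cycle for the
telemedical alarm probability. This calibration runs automatically whenever
`worsening_prob_per_day` or `tm_alarm_prob_per_cycle` is omitted from a
configuration, so the published calibration targets hold exactly whatever
branch probabilities are assumed. Explicit values are never overwritten.

Two readings of the period probability are possible — patients with at
least one admission, or admissions per patient. The packaged default treats
it as the per-period probability of (at least one) admission per patient,
which the calibration reproduces at the daily level; since the period length
is itself a configuration field (`reference_period_days`), either reading
can be imposed by overriding it together with the trigger probabilities.

## Parameters and defaults

Published values in the packaged scenarios: median ward stay 10 days
(conventional) vs 6.5 (telemedical); median ICU stay 2 days; ICU involvement
12.6 %; in-hospital mortality 7.1 %; GP visits 1.42 vs 2.84 and specialist
visits 0.30 vs 0.46 per patient-year; GP 25 €, specialist 31 €; case flat
rate 1523 € with trim points 4–12 days; ICU supplement 2496 € for a median
2-day stay; financing A 100 €/patient/month, financing B 1000 € per system +
500 €/month overhead + 40 €/patient/month. Visit rates are read as visits
per patient-year and modelled as a homogeneous Poisson process independent
of worsening-triggered contacts (the published counts are taken as the
routine baseline; whether they include triggered contacts is not stated).

Everything else is an explicit assumption, labelled as such in the YAML
fixtures: emergency fraction 0.10; branch split 0.20 medication change /
0.40 doctor / 0.25 specialist / 0.15 ambulance; improvement 0.60; referral
0.50; extramural mortality 0.02 (toggled off in the reference scenarios);
procedure probability 0.05 over a two-entry catalogue (2 500 and 5 000
points, 70/30); discharge transition 0.40 improve / 0.45 stay / 0.15
worsen; intervention success and face-to-face adaptation 0.70 each;
telemedical contact split 0.40/0.40/0.20. These were chosen once as
plausible mid-range values for a heart-failure population; the calibration
above makes the headline admission rates insensitive to them, but the mix
of outcome kinds (and hence outpatient tariffs, a small cost share) is not.
All four per-class parameter bundles use the arm-level values, because the
source reports cohort-level rates only; class-specific refinements are a
configuration edit away (`nyha_params.class_3: ...`).

## Numerical choices

* **Length of stay** is log-normal parameterised by its continuous median
  (`exp(meanlog) = median`), log-sd `los_log_sigma = 0.5` by default,
  rounded *up* to whole days with a floor of 1. Only medians are published;
  the log-normal gives the right skew typical of stay data, and `sigma = 0`
  degenerates to a fixed `ceiling(median)` for exact testing. Rounding up
  makes the integer median of the 6.5-day arm equal 7.
* **Money** is integer euro cents inside the engine; every scenario total is
  the exact sum of its cost lines. Inpatient cost lines are stamped at the
  admission day (case flat rates are billed per case), which also sidesteps
  censoring ambiguity for stays crossing the horizon end.
* **Months** for financing accrual are 30.4375 days (365.25/12). Fees are
  charged at each month start for patients alive that day — i.e. prorated to
  whole months survived; variant-B cohort overhead runs for the whole
  horizon as a system-level contract, and its monthly line is cohort-level
  (the per-patient component is the physician fee).
* **Death during a stay** truncates it at a day drawn uniformly within the
  sampled stay; ICU days are taken to lie at the start of the stay (severity
  is highest at admission), which only affects the ward/ICU split of
  truncated stays. Mortality, ICU and procedure draws are independent given
  the NYHA class, which is the only severity coupling the source describes.
* **Trim logic** applies to total in-hospital days (ward + ICU); ICU time is
  paid through the daily supplement on top. The published 1523 € is read as
  the within-trim flat amount and 2496 € as the cost of a median (2-day) ICU
  stay, i.e. 1248 €/day — both overridable. The per-day supplement beyond
  the upper trim (100 points/day) and the short-stay fraction (0.5) are
  assumptions; neither is published.
* **RNG** is one named Mersenne-Twister substream per patient per pathway
  (`rng_stream(seed, "run001/patient000017/outpatient")`), so identical
  seeds replay bit-identical results and enlarging the cohort never
  perturbs existing patients. Runs and arms use disjoint substreams — no
  common random numbers across arms, so paired comparisons carry full
  Monte-Carlo variance (the per-run spread is reported alongside means).
* **Break-even** is computed on the mean cumulative series (matching
  mean-of-runs reporting) as the *first* day the initially dearer curve
  falls to or below the comparator. Because monthly fees make the
  telemedical curve a sawtooth, an early transient crossing can satisfy
  this definition without a sustained one — as in the packaged comparison,
  where the telemedical arm ends ~27 % dearer yet a day-26 first crossing
  exists. Inspect the curves (`autoplot()`) before quoting a break-even
  day.
* **Yearly slices** are days [0, 365), [365, 730), [730, 1095).

## What the reference scenarios do and do not show

The packaged scenarios reproduce the published *inputs* exactly (the test
suite and `scripts/acceptance.R` recover every one of them from large
seeded simulations: medians of stay within ±1 day, event fractions within
3-sigma binomial bounds at n = 10⁵). The headline *outcomes* of the original
comparison — savings of up to 8 % by year three and a two-year break-even —
additionally depend on event and transition probabilities that were never
published; under this package's documented assumptions the telemedical
arm's inpatient savings (~700 €/patient-year) stay below the variant-A
system cost (1 200 €/patient-year), so telemedical care remains dearer
throughout while reproducing the qualitative pattern (dearer in year 1;
financing variant B front-loaded but cheaper than A over three years; fewer
admissions and roughly half the deaths under monitoring). Users with access
to better branch probabilities can drop them into the YAML files and rerun.

The generator also simplifies real data in ways that matter for
interpretation: no seasonality, no adherence or transmission failures, no
waiting times or bed capacity, no medication or travel costs, visit rates
independent of disease trajectory, and parameter homogeneity across NYHA
classes. Passing tests therefore demonstrate internal consistency and
faithful calibration, not external validity for any particular health
system.

## Problem sizes

The default test and acceptance runs use the full reference cohort (100
patients × 1 095 days × 10 runs × both arms) for scenario-level checks and
10⁴–10⁵ draws for kernel-level recovery; unit tests use 1–20-patient
cohorts over 30–400 days. These sizes were chosen so every stochastic check
sits comfortably inside its 3-sigma band while the whole suite stays fast.

## Known limitations

Single-step NYHA moves only; one LDF group per class rather than the full
catalogue; no probabilistic sensitivity analysis (one-at-a-time sweeps via
`sensitivity_sweep()` only); extramural mortality is modelled but disabled
in the reference scenarios, mirroring the published scenario scope.
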