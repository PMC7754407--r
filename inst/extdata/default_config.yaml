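# Default model configuration.
#
# The provenance block at the bottom separates inputs taken from the source
# sample and report (paper) from clearly-labelled placeholder inputs
# (placeholder): the reference transition probabilities, mortality rates,
# annual costs and sensitivity ranges come from a supplementary inputs table
# that is not publicly printed, so the values below are plausible
# stand-ins of the same shape and role. Every result that depends on them is
# interpreted through model properties, not through their absolute size.

meta:
  description: Policy trauma cost model - default inputs
  currency: 2018 USD

# Synthetic-cohort data-generating process (marginals of the reference
# sample of 458 trauma-exposed migrant children).
cohort:
  n: 458
  seed: 20180401
  age_mean: 13
  age_sd: 4
  prop_male: 0.430
  trauma_mean: 3.6
  trauma_sd: 2.3
  trauma_max: 20
  or_per_trauma: 1.232
  beta_age: 0.0
  beta_sex: 0.0

# Adjusted per-trauma-type odds ratio of occupying a more severe state,
# with 95% confidence bounds (adjusted for age and sex).
effect:
  or: 1.232
  ci_low: 1.141
  ci_high: 1.330

# Baseline state occupancy of the reference sample (counts; shares
# 13.1% / 38.2% / 29.3% / 19.4%).
baseline_states:
  Q1: 60
  Q2: 175
  Q3: 134
  Q4: 89

# State-conditional diagnosis counts (denominators = baseline_states).
prevalence_counts:
  ptsd: [21, 60, 70, 44]
  depression: [7, 32, 34, 36]
  anxiety: [4, 12, 15, 8]
  adhd: [1, 2, 6, 1]

# Policy scenarios: fraction of children exposed to extra policy-related
# trauma(s).
scenarios:
  - name: NoDetention
    exposed_fraction: 0.0
    extra_traumas: 1
  - name: FamilyDetention
    exposed_fraction: 0.5
    extra_traumas: 1
  - name: ZeroTolerance
    exposed_fraction: 1.0
    extra_traumas: 1

markov:
  start_age: 13
  horizons: [5, 10]
  progression_only: true
  # Annual progression probabilities among living states (placeholder).
  transition_matrix:
    - [0.92, 0.08, 0.00, 0.00]
    - [0.00, 0.94, 0.06, 0.00]
    - [0.00, 0.00, 0.95, 0.05]
    - [0.00, 0.00, 0.00, 1.00]

# Age-based annual probability of death (placeholder values of the order of
# U.S. child and young-adult all-cause mortality).
mortality:
  ages: [3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20,
         21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34, 35, 36,
         37, 38, 39, 40]
  rates: [0.00012, 0.00012, 0.00012, 0.00012, 0.00012, 0.00012, 0.00012,
          0.00017, 0.00017, 0.00017, 0.00017, 0.00017, 0.00060, 0.00060,
          0.00060, 0.00060, 0.00060, 0.00090, 0.00090, 0.00090, 0.00090,
          0.00090, 0.00110, 0.00110, 0.00110, 0.00110, 0.00110, 0.00110,
          0.00110, 0.00110, 0.00110, 0.00110, 0.00110, 0.00110, 0.00110,
          0.00110, 0.00110, 0.00110]

# Annual costs, 2018 USD (placeholder). direct = health sector;
# indirect = societal add-on (time, caregiver absenteeism, transportation).
costs:
  base_no_problems:
    direct: 1038
    indirect: 432
  base_behavior_problems:
    direct: 2528
    indirect: 1314
  conditions:
    ptsd:
      direct: 2386
      indirect: 1590
    depression:
      direct: 4824
      indirect: 2412
    anxiety:
      direct: 1728
      indirect: 972
    adhd:
      direct: 2112
      indirect: 1404
  include_q1_conditions: false

discount_rate: 0.0

# Hypothetical policy-affected cohorts for budget impact.
cohorts:
  - label: Cohort1
    size: 2342
  - label: Cohort2
    size: 16790
  - label: Cohort3
    size: 23725

# One-way deterministic sensitivity analysis (tornado) settings.
dsa:
  outcome: per_child
  scenario: ZeroTolerance
  perspective: direct
  horizon: 5
  ranges:
    - path: costs.conditions.depression.direct
      low: 2412
      high: 9648
    - path: costs.conditions.ptsd.direct
      low: 1670
      high: 3102
    - path: costs.conditions.anxiety.direct
      low: 1210
      high: 2246
    - path: costs.conditions.adhd.direct
      low: 1478
      high: 2746
    - path: costs.base_behavior_problems.direct
      low: 1770
      high: 3286
    - path: effect.or
      low: 1.141
      high: 1.330

sweep:
  increment: 0.1
  horizon: 5

# Probabilistic sensitivity analysis: distribution families chosen by
# parameter support (lognormal for the odds ratio, gamma for costs, beta
# for the exposed fraction).
psa:
  iterations: 10000
  seed: 20180402
  parameters:
    - path: effect.or
      dist: lognormal
      meanlog: 0.20855224
      sdlog: 0.03909645
    - path: costs.conditions.depression.direct
      dist: gamma
      mean: 4824
      cv: 0.25
    - path: costs.conditions.ptsd.direct
      dist: gamma
      mean: 2386
      cv: 0.25
    - path: costs.base_behavior_problems.direct
      dist: gamma
      mean: 2528
      cv: 0.25
    - path: scenarios.2.exposed_fraction
      dist: beta
      shape1: 25
      shape2: 25

provenance:
  paper: [cohort, effect, baseline_states, prevalence_counts, scenarios,
          markov.start_age, markov.horizons, cohorts]
  placeholder: [markov.transition_matrix, mortality, costs, dsa.ranges,
                psa.parameters]
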