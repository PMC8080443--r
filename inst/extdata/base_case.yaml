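# Canonical base-case configuration: secondary prevention after MI,
# Chinese healthcare perspective, all monetary values in 2019 CNY.
model:
  horizon: 25                      # years (1-year cycles)
  discount_rate: 0.05              # applied to costs and QALYs alike
  starting_age: 60                 # cohort age at model entry (years)
  drug_cost_accrual: fixed_horizon # fixed_horizon | alive
  cv_death_cost: annual            # annual | entry
  effect_application: hazard       # hazard | probability

population:
  # First-year annual event probabilities (real-world post-MI cohort,
  # 1-year follow-up).
  base_rates:
    non_fatal_mi: 0.017
    non_fatal_is: 0.009
    cv_death: 0.022
    non_cv_death: 0.009
  # Age escalation: rates are multiplied by one growth factor per
  # completed 5-year block of attained age past reference_age. The
  # supplementary per-year risk table behind the published analysis is
  # not public; these factors are the package's reconstruction,
  # calibrated so the schedule reproduces the published base-case
  # results and scenario orderings within demographically plausible
  # bounds: non-fatal event incidence grows steeply with attained age,
  # post-MI cardiovascular case fatality grows more gently (the acute
  # excess dominates the first-year rate), and growth decelerates at
  # extreme old age. Blocks are attained-age bands past reference_age;
  # the last factor is recycled beyond the list.
  reference_age: 60
  block_years: 5
  growth_factors:
    non_fatal_mi: [1.6, 1.6, 1.6, 1.6, 1.36, 1.18, 1.06, 1.0]
    non_fatal_is: [1.6, 1.6, 1.6, 1.6, 1.36, 1.18, 1.06, 1.0]
    cv_death: [1.4, 1.4, 1.4, 1.4, 1.24, 1.12, 1.04, 1.0]
    non_cv_death: [1.1, 1.1, 1.1, 1.1, 1.06, 1.03, 1.01, 1.0]
  # Subgroup risk scaling; 1.0 = general post-MI population.
  rate_multipliers:
    non_fatal_mi: 1.0
    non_fatal_is: 1.0
    cv_death: 1.0
    non_cv_death: 1.0

# Per-state annual costs (CNY/year) and utility weights; ranges are the
# one-way/probabilistic sensitivity ranges (costs +/- 25%, utilities 95% CI).
states:
  EVENT_FREE:
    annual_cost: 8344
    cost_range: [6258, 10430]
    utility: 0.824
    utility_range: [0.800, 0.848]
  ACUTE_MI:
    annual_cost: 71030
    cost_range: [53272, 88787]
    utility: 0.672
    utility_range: [0.625, 0.719]
  POST_MI:
    annual_cost: 8344
    cost_range: [6258, 10430]
    utility: 0.824
    utility_range: [0.800, 0.848]
  ACUTE_IS:
    annual_cost: 22342
    cost_range: [16756, 27927]
    utility: 0.327
    utility_range: [0.264, 0.390]
  POST_IS:
    annual_cost: 8463
    cost_range: [6347, 10578]
    utility: 0.524
    utility_range: [0.472, 0.576]
  CV_DEATH:
    # Weighted average cost of fatal MI and fatal stroke; accrual mode
    # set by model.cv_death_cost.
    annual_cost: 77811
    cost_range: [58358, 97263]
    utility: 0.0
  NONCV_DEATH:
    annual_cost: 0
    utility: 0.0

# Component fatal-event costs behind the weighted CV-death cost (metadata).
fatal_event_costs:
  fatal_mi: 87756
  fatal_stroke: 59025

threshold:
  wtp: 212676            # CNY per QALY
  gdp_per_capita: 70892  # 2019 per-capita GDP; wtp = multiplier x GDP
  multiplier: 3

strategies:
  statin:
    label: "Statins therapy alone"
    drug_cost: 0
    effect: none
  alirocumab:
    label: "Alirocumab added to statins therapy"
    drug_cost: 34355       # discounted net price (33% rebate), CNY/year
    drug_cost_full: 51532  # full list price, CNY/year
    effect: alirocumab
    utility_penalty: -0.0003
    utility_penalty_range: [-0.002, 0.0]
    # Injection-site reaction incidences recorded as metadata only; the
    # model applies the constant utility decrement above.
    injection_site_incidence:
      treated: 0.038
      placebo: 0.021
  ezetimibe:
    label: "Ezetimibe added to statins therapy"
    drug_cost: 2827
    effect: ezetimibe

effects:
  alirocumab:
    # Clinical-endpoint hazard ratios (trial follow-up).
    hr_clinical:
      non_fatal_mi: {point: 0.86, ci: [0.77, 0.96]}
      non_fatal_is: {point: 0.73, ci: [0.57, 0.93]}
      cv_death:     {point: 0.88, ci: [0.74, 1.05]}
    # Relative risks derived from the LDL-C-reduction hypothesis.
    rr_ldl:
      non_fatal_mi: {point: 0.57, ci: [0.53, 0.63]}
      non_fatal_is: {point: 0.66, ci: [0.59, 0.75]}
      cv_death:     {point: 0.77, ci: [0.71, 0.83]}
    # All-cause-death efficacy variant (scenario): replaces the death
    # effects in both death transitions.
    all_cause: {point: 0.85, ci: [0.73, 0.98]}
    # Optional derivation layer: rr = rr_per_mmol ^ delta_ldl must
    # reproduce the rr_ldl block above. Neither input is published with
    # the analysis; this pair is a calibrated reconstruction.
    ldl_derivation:
      delta_ldl: 1.8           # absolute LDL-C reduction, mmol/L
      rr_per_mmol:
        non_fatal_mi: 0.731771
        non_fatal_is: 0.793865
        cv_death: 0.864847
  ezetimibe:
    # Non-fatal HRs from ezetimibe outcome-trial literature and the
    # assumed LDL-C reduction are not printed with the analysis;
    # placeholder values, structural use only.
    external_unverified: true
    hr_clinical:
      non_fatal_mi: {point: 0.87, ci: [0.80, 0.95]}
      non_fatal_is: {point: 0.79, ci: [0.67, 0.94]}
    ldl_derivation:
      delta_ldl: 0.45          # mmol/L, assumed
      rr_per_mmol:
        non_fatal_mi: 0.731771
        non_fatal_is: 0.793865
        cv_death: 0.864847
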