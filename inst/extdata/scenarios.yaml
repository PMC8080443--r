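# Scenario grid: each entry is merged over the base-case configuration.
# Subgroup risk multipliers and subgroup-specific effects marked
# external_unverified are placeholders (their sources are not published
# with the analysis); they exercise the pipeline structurally and are
# not numeric reproduction targets.

all_cause_death:
  label: "Reduction in non-cardiovascular death"
  modes: [hr_clinical, rr_ldl]
  all_cause: true

ezetimibe_comparator:
  label: "Ezetimibe added to statins therapy group"
  modes: [hr_clinical, rr_ldl]
  comparator: ezetimibe

female:
  label: "Female population"
  modes: [hr_clinical, rr_ldl]
  external_unverified: true
  overrides:
    population:
      rate_multipliers:
        non_fatal_mi: 1.0
        non_fatal_is: 1.0
        cv_death: 1.4
        non_cv_death: 1.4

fh:
  label: "FH with MI"
  modes: [rr_ldl]
  overrides:
    population:
      rate_multipliers:
        non_fatal_mi: 2.3
        non_fatal_is: 2.3
        cv_death: 2.3
        non_cv_death: 1.0

polyvascular:
  label: "Polyvascular disease (3 beds)"
  modes: [hr_clinical]
  external_unverified: true
  overrides:
    population:
      rate_multipliers:
        non_fatal_mi: 1.8
        non_fatal_is: 1.8
        cv_death: 1.8
        non_cv_death: 1.0
  effect_override:
    cv_death: 0.23
    non_cv_death: 0.23

diabetes:
  label: "DM with MI"
  modes: [hr_clinical, rr_ldl]
  external_unverified: true
  overrides:
    population:
      rate_multipliers:
        non_fatal_mi: 1.5
        non_fatal_is: 1.5
        cv_death: 1.5
        non_cv_death: 1.0

hypertension:
  label: "Hypertension with MI"
  modes: [hr_clinical, rr_ldl]
  external_unverified: true
  overrides:
    population:
      rate_multipliers:
        non_fatal_mi: 1.3
        non_fatal_is: 1.3
        cv_death: 1.3
        non_cv_death: 1.0

age_65:
  label: "Starting age 65 years"
  overrides: {model: {starting_age: 65}}
age_70:
  label: "Starting age 70 years"
  overrides: {model: {starting_age: 70}}
age_75:
  label: "Starting age 75 years"
  overrides: {model: {starting_age: 75}}
age_80:
  label: "Starting age 80 years"
  overrides: {model: {starting_age: 80}}

horizon_5:
  label: "Time horizon 5 years"
  overrides: {model: {horizon: 5}}
horizon_10:
  label: "Time horizon 10 years"
  overrides: {model: {horizon: 10}}
horizon_20:
  label: "Time horizon 20 years"
  overrides: {model: {horizon: 20}}
horizon_30:
  label: "Time horizon 30 years"
  overrides: {model: {horizon: 30}}

discount_3_5:
  label: "Discount rate 3.5%"
  overrides: {model: {discount_rate: 0.035}}
discount_6:
  label: "Discount rate 6%"
  overrides: {model: {discount_rate: 0.06}}
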