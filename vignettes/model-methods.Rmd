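---
title: "Model and methods: a Markov cohort cost-effectiveness model of alirocumab after myocardial infarction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsk9cea)
```

## The decision problem

PCSK9 inhibitors lower LDL cholesterol far below what statins achieve and
reduce recurrent ischaemic events after myocardial infarction (MI), but at a
list price that dwarfs every other component of post-MI care. From the
Chinese healthcare perspective this package asks: for a cohort of patients
discharged after MI on statin therapy, is adding alirocumab worth its annual
price — and if not, at what price would it be? The decision standard is the
conventional Chinese willingness-to-pay (WTP) threshold of three times
per-capita GDP, 212,676 CNY per quality-adjusted life-year (QALY).

## Model structure

The engine is a Markov cohort state-transition model with seven states and
annual cycles:

* `EVENT_FREE` — post-MI on therapy, no further event;
* `ACUTE_MI`, `ACUTE_IS` — one-year tunnel states entered upon a non-fatal
  recurrent MI or ischaemic stroke (IS), carrying the acute-year cost and
  utility;
* `POST_MI`, `POST_IS` — chronic sequela states entered from the acute
  tunnels;
* `CV_DEATH`, `NONCV_DEATH` — absorbing death states.

Every living state faces the same four annual event probabilities
(non-fatal MI, non-fatal IS, cardiovascular death, non-cardiovascular
death); residual mass stays in place, with acute states settling into
their post states. Recurrence is memoryless: the current state is defined
by the most recent event, so cross-over events (an IS after an MI, and vice
versa) are permitted and no composite states are priced. The acute/post
split is the only structure consistent with distinct acute-year and
chronic-year costs and utilities.

If the effect-adjusted event probabilities of any cycle sum above one the
run aborts naming the cycle; the engine never renormalizes silently.

All state time is half-cycle corrected: each cycle is credited with the
mean of its start and end occupancies (trapezoid convention), treating
transitions as occurring mid-cycle on average. Outcomes in cycle *t*
(1-indexed) are discounted by $(1+r)^{-t}$ with $r = 5\%$ per year for
costs and QALYs alike.

## Inputs

All inputs live in one versioned YAML configuration
(`inst/extdata/base_case.yaml`), loaded by `base_case_config()`. Monetary
values are 2019 CNY; probabilities are annual.

* **First-year event rates** (real-world Chinese post-MI cohort): non-fatal
  MI 1.7%, non-fatal IS 0.9%, CV death 2.2%, non-CV death 0.9%.
* **Treatment effects** under two efficacy hypotheses: clinical-endpoint
  hazard ratios from trial follow-up (MI 0.86, IS 0.73, CV death 0.88), or
  relative risks derived from the LDL-C-reduction hypothesis (0.57, 0.66,
  0.77). Effects multiply hazards, not probabilities:
  $p' = 1-(1-p)^m$, the proportional-hazards reading of trial ratios
  (direct probability multiplication is available as
  `model.effect_application: probability` for structural sensitivity).
  Non-CV death is untreated except in the all-cause-death scenario, which
  routes the all-cause mortality effect (HR 0.85) to both death
  transitions — the only reading under which "all-cause" differs from the
  base case.
* **Costs**: per-state annual costs (event-free 8,344; acute MI 71,030;
  post-MI 8,344; acute IS 22,342; post-IS 8,463) and the weighted
  fatal-event cost 77,811 on the CV-death state. Annual drug prices:
  alirocumab 51,532 (full list) and 34,355 (discounted net, 33% rebate);
  ezetimibe 2,827.
* **Utilities**: event-free/post-MI 0.824, acute MI 0.672, acute IS 0.327,
  post-IS 0.524; a constant annual decrement of 0.0003 on the alirocumab
  arm for injection-site reactions (no cost and no discontinuation; the
  underlying incidences, 3.8% vs 2.1%, are stored as metadata only).

## Two accrual conventions worth spelling out

Two conventions in this model depart from textbook defaults; both are
forced by the arithmetic of the results the model is built to reproduce,
and both are configurable.

**Drug cost is a fixed-horizon payment stream.** The annual price is paid
over the whole 25-year horizon, discounted with half-cycle correction,
independent of survival (`model.drug_cost_accrual: fixed_horizon`). The
reproduction target prints an incremental-cost gap between the two price
settings of 248,144 CNY that is identical under both efficacy hypotheses;
that gap equals the price difference (17,177 CNY) times
$\sum_{t=1}^{25}\tfrac{(1+r)^{-(t-1)}+(1+r)^{-t}}{2} = 14.44629$ — the
full-horizon half-cycle discount sum — to within one CNY, and the printed
value-based prices back-solve exactly under this convention. Survival-
dependent accrual (`alive`, in which patients dying mid-cycle pay half a
year) is available and yields drug-years of roughly 9 instead of 14.45.

**The fatal-event cost recurs in the CV-death state.** The weighted
fatal-event cost (77,811 CNY) is carried as an annual reward on `CV_DEATH`
(`model.cv_death_cost: annual`); a literal one-time entry cost is available
as `entry`. The recurring convention is what the reproduced cost totals
imply: it accounts for both the level of the comparator arm's total cost
and the small negative event-cost offset inside the incremental cost. With
the `entry` convention the comparator arm total falls by roughly two
thirds.

Because the QALY side is unaffected by either convention, value-based
prices react only through the incremental cost.

## The reconstructed event-rate schedule

The per-year 25-year risk table behind the reproduced analysis is not
public; only the first-year rates and the statement that they grow every
five years in line with age-specific natural mortality are. The package
therefore ships a reconstruction (`build_schedule()`): rates are
piecewise-constant over 5-year blocks of *attained age* and multiply by one
growth factor per completed block past the reference age (60), the last
factor recycling for very old ages.

The shipped factors are calibrated, once, against the full set of printed
constraints the schedule must satisfy jointly — the base-case
cost-effectiveness surface to within ±10% and the scenario orderings
(ICER falling with starting age 65→80, rising as the horizon shortens,
value-based price falling as the discount rate rises):

* non-fatal MI and IS: ×1.6 per block;
* CV death: ×1.4 per block;
* non-CV death: ×1.1 per block;
* all decelerating after the fourth block (ages 85+).

The asymmetry is epidemiologically defensible: the first-year post-MI
death rate already contains a large acute excess, so its growth with age
is flatter than raw Gompertz mortality doubling, while morbidity keeps
rising and the cardiovascular share of mortality grows with age. A uniform
demographic factor (mortality doubling every ~8 years, ×1.54 per block)
reproduces the base-case levels but *inverts* the starting-age ordering;
that diagnosis is what motivated the per-endpoint calibration. The
schedule remains flagged as a reconstruction: base-case levels carry a
±10% band, and scenario results are interpreted as orderings, not point
values.

Starting-age scenarios shift the escalation so it tracks attained age (an
80-year-old entrant starts at already-escalated rates); long horizons
extend the schedule by recycling the last factor.

## Outcome accumulation and the value-based price

`accumulate_outcomes()` produces, per arm: discounted total cost (state
annual costs on corrected state time, one-time entry rewards on entrants,
plus the drug stream), discounted QALYs (state utilities plus the
disutility on alive time), discounted life-years, and drug-years (the
multiplier of the annual price). `cea_compare()` forms incremental cost,
incremental QALYs and their ratio on full-precision values — never on
rounded reports — with dominance flags instead of division when the QALY
difference is zero.

`value_based_price()` solves for the annual price at which the ICER equals
the WTP threshold by bisection to 1 CNY, asserting that the ICER is
increasing in price over the bracket. Since total cost is linear in price
and QALYs are price-invariant, the solution is independent of the price
setting used elsewhere; re-running the model at the solved price returns
the threshold ICER to within $10^{-4}$ relative.

## Sensitivity analysis

**One-way (tornado).** Each cost, utility and disutility parameter is set
to the endpoints of its plausible range (costs ±25%, utilities their 95%
CIs) with everything else at base case — exactly two model evaluations per
parameter — and parameters are ranked by absolute ICER span. Treatment
effects are excluded by default because the two efficacy hypotheses are
explored as structural modes (and in the PSA); `include_effects = TRUE`
sweeps their CIs too. Endpoint ICERs are reported without interpolation;
they may be non-monotone in utility parameters.

**Probabilistic (PSA).** `run_psa()` draws independent joint parameter
sets: log-normals for effects and costs (CI-matching fit anchored at the
median, $\sigma = (\ln hi - \ln lo)/(2 \times 1.959964)$; mean-anchoring
available behind a flag), betas for utilities (method of moments from mean
and CI-derived SD), and a beta on the reflected interval $[-0.002, 0]$ for
the injection-site disutility, whose declared support is negative. Event
rates are never sampled; they vary only through age escalation. The
reference arm's cohort trace does not depend on sampled parameters, so it
is computed once and re-costed per draw; treated-arm traces are rebuilt
per draw. The whole analysis is a pure function of (config, seed, draw
count).

**Acceptability.** Curves are computed from net monetary benefit
(`wtp × QALYs − cost`): pairwise (probability the add-on beats the
comparator) and multi-strategy (probability of maximal NMB; probabilities
partition the draws). A caution for interpretation: with the
survival-independent drug stream, the incremental cost is ~470k CNY
essentially regardless of the parameter draw, so NMB-positivity at the
212,676 threshold would require an incremental QALY gain above ~2.2 —
more than ten standard deviations beyond the sampled distribution. The
model's acceptability at the threshold is therefore essentially zero, and
small positive acceptability frequencies reported for models of this shape
cannot arise from the stated distributions under the NMB definition; the
package does not adopt an alternative definition to manufacture one.

## Scenario grid

`scenario_grid()` runs named configuration overlays through the full
pipeline: the all-cause-death efficacy variant; ezetimibe as an active
comparator (its non-fatal-event HRs and assumed LDL-C reduction are not
published with the reproduced analysis and ship as placeholders flagged
`external_unverified`, composed with the LDL-derived CV-death RR);
high-risk subgroups via per-endpoint event-rate multipliers (FH ×2.3 on
MACE; female, diabetes, hypertension and polyvascular multipliers are
placeholders, the last combined with a subgroup-specific mortality effect
of 0.23 on both death transitions); starting ages 65–80; horizons 5–30
years; and discount rates 3.5%/6%. Subgroup results built on placeholder
inputs are exercised structurally (orderings, reproducibility), never as
numeric targets.

## What the generator emulates — and what it does not

The synthetic-input layer reproduces the *statistical shape* the analysis
assumes: age-escalated annual probabilities, multiplicative subgroup risk,
CI-matched parameter uncertainty, and (for engine testing) small random
cohort models with stochastic rows and an absorbing death state
(`generate_toy_model()`, cross-checked against a million-patient
microsimulation). It does not emulate patient-level heterogeneity,
adherence or discontinuation, within-cycle event sequencing finer than a
year, correlation between sampled parameters, or baseline LDL-C strata.
Passing tests therefore show the pipeline computes its estimands
correctly under these study conditions — not that those conditions capture
every feature of real post-MI populations.

## Numerical choices and degenerate inputs

* Stochasticity of every transition row is checked to $10^{-12}$; trace
  mass conservation to $10^{-9}$.
* Degenerate CIs (low = point = high) give zero-variance fits whose draws
  all equal the point; infeasible beta variances error rather than clip.
* Zero QALY differences yield dominance flags, never division.
* Bisection brackets for the value-based price are validated at both ends
  (threshold attainable, ICER increasing); tolerance 1 CNY.
* Ties in multi-strategy NMB are broken toward the first-listed strategy;
  with continuous distributions they have measure zero.

## Problem sizes used by the test suite

The suite runs the deterministic pipeline at its native size (25 cycles,
well under a second per run), a 10,000-draw PSA for the acceptability
check, $10^5$ draws per parameter for distribution-fit checks,
$10^6$ simulated patients for the microsimulation cross-check on 3-state
toy models, and 10,000 random toy-model specifications for the
feasibility property.

## Known limitations

* The event-rate schedule is a calibrated reconstruction; base-case
  levels inherit a ±10% band and subgroup rows built on placeholder
  inputs are structural only.
* The fixed-horizon drug stream and recurring fatal-event cost are
  faithful to the reproduced totals but are not the conventions a de novo
  model would choose; both have switchable alternatives.
* No adherence, discontinuation, legacy effect, or baseline-LDL-C
  stratification; results do not generalize to primary prevention.
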