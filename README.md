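# pcsk9cea

Cost-effectiveness modelling of the PCSK9 inhibitor alirocumab added to
statin therapy for secondary prevention after myocardial infarction (MI),
from the Chinese healthcare perspective.

The package is aimed at health-economic modellers and HTA analysts. It
implements a seven-state Markov cohort model (event-free, acute/post
non-fatal MI, acute/post non-fatal ischaemic stroke, cardiovascular and
non-cardiovascular death) over annual cycles with half-cycle correction
and 5% annual discounting of costs and QALYs. On top of the engine it
provides:

* the deterministic base case: total and incremental discounted cost and
  QALYs, and the incremental cost-effectiveness ratio
  ICER = ΔC/ΔQ, under two efficacy hypotheses — clinical-endpoint hazard
  ratios applied as hazard multipliers, p′ = 1 − (1 − p)^HR, or relative
  risks derived from LDL-C reduction via RR = RR_per_mmol^ΔLDL;
* value-based pricing: bisection for the annual price at which the ICER
  equals the willingness-to-pay threshold (212,676 CNY/QALY, three times
  2019 per-capita GDP);
* one-way deterministic sensitivity analysis (tornado ranking by ICER
  span) and a seeded probabilistic sensitivity analysis with log-normal /
  beta parameter distributions fitted from printed ranges, plus
  cost-effectiveness acceptability curves based on net monetary benefit
  NMB = WTP × QALY − cost;
* a scenario grid: all-cause-mortality efficacy variant, ezetimibe
  comparator, high-risk subgroups, starting ages 65–80, horizons 5–30
  years, discount rates 3.5%/6%.

All inputs (event rates, effects, costs, utilities, prices, threshold)
live in a versioned YAML configuration shipped with the package. The
25-year age-escalated event-rate schedule is a documented reconstruction
built from the first-year rates and five-yearly growth factors; see the
methods vignette (`vignettes/model-methods.Rmd`) for its calibration and
the package's accrual conventions.

## Worked example

```r
library(pcsk9cea)

cfg <- base_case_config()
bc  <- run_base_case(cfg)
subset(bc, price == "base" & strategy == "alirocumab",
       c(mode, inc_cost, inc_qaly, icer, vbp))
#>          mode inc_cost  inc_qaly    icer       vbp
#> 2 hr_clinical 471770.7 0.2953815 1597157  6046.677
#> 6      rr_ldl 444717.2 0.5393284  824576 11510.849
```

Read: at the discounted net price (34,355 CNY/year), adding alirocumab
costs an extra ~471,771 CNY and gains ~0.295 QALYs per patient over 25
years under the clinical-endpoint hypothesis — an ICER of ~1.60 million
CNY/QALY, far above the 212,676 threshold. The annual price would have to
fall to ~6,047 CNY (an 88% reduction from the 51,532 list price) to meet
the threshold; under the more optimistic LDL-C-reduction hypothesis the
value-based price is ~11,511 CNY.

```r
tw <- tornado(cfg)
head(tw[, c("parameter", "span")], 3)
#>                               parameter      span
#> 1             states.EVENT_FREE.utility 131571.87
#> 2 strategies.alirocumab.utility_penalty 112912.39
#> 3                states.POST_IS.utility  64086.88

psa <- run_psa(cfg, n_draws = 1000, seed = 1)
acceptability(psa)   # probability cost-effective at 212,676 CNY/QALY
#> [1] 0
```

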