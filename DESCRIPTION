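Package: pcsk9cea
Title: Cost-Effectiveness of PCSK9 Inhibitor Add-On Therapy after
    Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort state-transition model for the health-economic
    evaluation of alirocumab added to statin therapy for secondary
    prevention after myocardial infarction in the Chinese setting.
    Implements the deterministic base case (costs, QALYs, incremental
    cost-effectiveness ratios), value-based price solving against a
    willingness-to-pay threshold, one-way deterministic sensitivity
    analysis (tornado), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and a scenario/subgroup
    grid (efficacy hypotheses, ezetimibe comparator, starting age,
    horizon, discount rate). All inputs are consumed from a versioned
    YAML configuration; an age-escalated event-rate schedule generator
    reconstructs the 25-year baseline risk table from first-year event
    rates and five-yearly growth factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
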