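null_effect <- structure(
  list(mode = "none",
       multipliers = c(non_fatal_mi = 1, non_fatal_is = 1,
                       cv_death = 1, non_cv_death = 1)),
  class = "treatment_effect")

zero_schedule <- function(horizon = 5) {
  s <- data.frame(cycle = seq_len(horizon), age = 60 + seq_len(horizon) - 1,
                  non_fatal_mi = 0, non_fatal_is = 0, cv_death = 0,
                  non_cv_death = 0)
  class(s) <- c("event_schedule", "data.frame")
  s
}

test_that("transition matrices are stochastic with the expected structure", {
  sched <- build_schedule(base_config())
  eff <- effect_for_arm(base_config(), "alirocumab", "hr_clinical")
  M <- build_transition_matrix(sched, eff, 1)
  expect_equal(rowSums(M), setNames(rep(1, 7), state_names()),
               tolerance = 1e-12)
  # death rows are unit vectors on themselves
  expect_equal(M["CV_DEATH", "CV_DEATH"], 1)
  expect_equal(M["NONCV_DEATH", "NONCV_DEATH"], 1)
  # hazard-convention effect adjustment on the treated arm
  expect_equal(M["EVENT_FREE", "ACUTE_MI"], 1 - (1 - 0.017)^0.86,
               tolerance = 1e-12)
  # non-CV death identical to baseline
  expect_equal(M["EVENT_FREE", "NONCV_DEATH"], 0.009)
  # acute states settle into post states
  expect_equal(M["ACUTE_MI", "POST_MI"],
               M["EVENT_FREE", "EVENT_FREE"])
  expect_gt(M["ACUTE_IS", "POST_IS"], 0.9)
})

test_that("zero event probabilities give identity rows for living states", {
  M <- build_transition_matrix(zero_schedule(), null_effect, 1)
  expect_equal(M["EVENT_FREE", "EVENT_FREE"], 1)
  expect_equal(M["POST_MI", "POST_MI"], 1)
  expect_equal(M["ACUTE_MI", "POST_MI"], 1)  # tunnel still resolves
})

test_that("a null effect reproduces the untreated matrix exactly", {
  sched <- build_schedule(base_config())
  hr1 <- structure(list(mode = "hr_clinical",
                        multipliers = c(non_fatal_mi = 1, non_fatal_is = 1,
                                        cv_death = 1, non_cv_death = 1)),
                   class = "treatment_effect")
  expect_identical(build_transition_matrix(sched, null_effect, 3),
                   build_transition_matrix(sched, hr1, 3))
})

test_that("adjusted probabilities summing above one abort with the cycle", {
  sched <- zero_schedule(3)
  sched$cv_death <- c(0.01, 0.7, 0.01)
  sched$non_cv_death <- 0.4
  expect_error(build_transition_matrix(sched, null_effect, 2), "cycle 2")
  init <- setNames(c(1, rep(0, 6)), state_names())
  expect_error(
    run_cohort(function(t) build_transition_matrix(sched, null_effect, t),
               init, 3),
    "cycle 2")
})

test_that("cohort traces conserve mass and never resurrect the dead", {
  cfg <- base_config()
  for (strategy in c("statin", "alirocumab")) {
    out <- run_strategy(cfg, strategy, keep_trace = TRUE)
    occ <- attr(out, "trace")$occupancy
    expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
    expect_true(all(diff(occ[, "CV_DEATH"]) >= -1e-12))
    expect_true(all(diff(occ[, "NONCV_DEATH"]) >= -1e-12))
    expect_true(all(occ >= -1e-12))
  }
})

test_that("an event-free cohort with no events stays event-free", {
  init <- setNames(c(1, rep(0, 6)), state_names())
  tr <- run_cohort(
    function(t) build_transition_matrix(zero_schedule(25), null_effect, t),
    init, 25)
  expect_equal(tr$occupancy[, "EVENT_FREE"], rep(1, 26))
  expect_equal(sum(tr$entrants), 0)
})

test_that("certain CV death in year one absorbs the whole cohort", {
  sched <- zero_schedule(3)
  sched$cv_death <- c(1, 0, 0)
  init <- setNames(c(1, rep(0, 6)), state_names())
  tr <- run_cohort(
    function(t) build_transition_matrix(sched, null_effect, t), init, 3)
  expect_equal(unname(tr$occupancy[2:4, "CV_DEATH"]), rep(1, 3))
  expect_equal(unname(tr$entrants[1, "CV_DEATH"]), 1)
  expect_equal(unname(tr$entrants[2:3, "CV_DEATH"]), c(0, 0))
})

test_that("base-case terminal occupancy matches a step-by-step recomputation", {
  cfg <- base_config()
  out <- run_strategy(cfg, "statin", keep_trace = TRUE)
  occ25 <- attr(out, "trace")$occupancy[26, ]
  oracle <- brute_force_occupancy(cfg)
  expect_equal(unname(occ25), oracle, tolerance = 1e-12)

  m <- effect_for_arm(cfg, "alirocumab", "hr_clinical")$multipliers
  out_t <- run_strategy(cfg, "alirocumab", keep_trace = TRUE)
  expect_equal(unname(attr(out_t, "trace")$occupancy[26, ]),
               brute_force_occupancy(cfg, m), tolerance = 1e-12)
})

test_that("half-cycle correction is the trapezoid of adjacent occupancies", {
  # constant occupancy: corrected weights equal occupancy
  init <- setNames(c(1, rep(0, 6)), state_names())
  tr <- run_cohort(
    function(t) build_transition_matrix(zero_schedule(4), null_effect, t),
    init, 4)
  w <- half_cycle_correct(tr)
  expect_equal(unname(w[, "EVENT_FREE"]), rep(1, 4))
  expect_equal(unname(rowSums(w)), rep(1, 4))

  # a one-cycle 1 -> 0 drop gives weight 0.5
  sched <- zero_schedule(2); sched$cv_death <- c(1, 0)
  tr2 <- run_cohort(
    function(t) build_transition_matrix(sched, null_effect, t), init, 2)
  expect_equal(unname(half_cycle_correct(tr2)[1, "EVENT_FREE"]), 0.5)

  # undiscounted corrected life-years equal the trapezoidal integral of
  # the survival curve (independent numerical-integration oracle)
  cfg <- base_config()
  cfg$model$discount_rate <- 0
  out <- run_strategy(validate_config(cfg), "statin", keep_trace = TRUE)
  alive <- rowSums(attr(out, "trace")$occupancy[, alive_states()])
  expect_equal(out$life_years, pracma::trapz(0:25, alive),
               tolerance = 1e-12)
})

test_that("discounting follows the fixed cycle convention", {
  expect_equal(discount_factor(0, 1:10), rep(1, 10))
  expect_equal(discount_factor(0.05, 1), 0.9523810, tolerance = 1e-7)
  expect_equal(discount_factor(0.05, 25), 0.2953028, tolerance = 1e-7)
  expect_error(discount_factor(-0.1, 1), ">= 0")
  expect_error(discount_factor(0.05, -1), "offset")

  # present value of 100 at cycle 2
  expect_equal(100 * discount_factor(0.05, 2), 90.70295, tolerance = 1e-5)
})

test_that("outcome accumulation matches closed forms on simple cohorts", {
  # one living state, utility 1, full occupancy, no discounting: 10 QALYs
  M <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "DEAD"), c("A", "DEAD")))
  tr <- run_cohort(function(t) M, c(1, 0), 10)
  states <- data.frame(name = c("A", "DEAD"), annual_cost = c(100, 0),
                       transition_cost = 0, utility = c(1, 0),
                       alive = c(TRUE, FALSE))
  out <- accumulate_outcomes(tr, states, 0)
  expect_equal(out$total_qaly, 10)
  expect_equal(out$life_years, 10)
  expect_equal(out$total_cost, 1000)

  # QALYs can never exceed life-years times the best utility
  cfg <- base_config()
  arm <- run_strategy(cfg, "alirocumab")
  expect_lte(arm$total_qaly, arm$life_years * 0.824)
  expect_gte(arm$total_qaly, 0)

  # dimension mismatch is caught
  expect_error(accumulate_outcomes(tr, rbind(states, states), 0),
               "dimensions")
})

test_that("drug cost accrual conventions differ as documented", {
  cfg <- base_config()
  fixed <- run_strategy(cfg, "alirocumab")
  cfg$model$drug_cost_accrual <- "alive"
  alive <- run_strategy(validate_config(cfg), "alirocumab")
  # the fixed-horizon stream covers the whole horizon regardless of
  # survival, so it costs more and its drug-years equal the half-cycle
  # discount sum
  expect_gt(fixed$total_cost, alive$total_cost)
  h <- 25; r <- 0.05
  expect_equal(fixed$drug_years,
               sum(((1 + r)^-(0:(h - 1)) + (1 + r)^-(1:h)) / 2),
               tolerance = 1e-12)
  expect_equal(alive$drug_years, alive$life_years, tolerance = 1e-12)
})

test_that("cohort outcomes agree with a million-patient microsimulation", {
  toy <- generate_toy_model(n_states = 3, horizon = 5, seed = 7)
  for (drug in unname(toy$strategies)) {
    engine <- run_toy_model(toy, drug_cost = drug, discount_rate = 0.05)
    oracle <- microsim_outcomes(toy$matrices, toy$init, toy$horizon,
                                toy$states, 0.05, drug_cost = drug,
                                n_patients = 1e6, seed = 123)
    expect_lt(abs(engine$total_cost - oracle$mean["cost"]),
              3 * oracle$se["cost"] + 1e-9)
    expect_lt(abs(engine$total_qaly - oracle$mean["qaly"]),
              3 * oracle$se["qaly"] + 1e-12)
    expect_lt(abs(engine$life_years - oracle$mean["ly"]),
              3 * oracle$se["ly"] + 1e-12)
  }
})
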