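#' Per-cycle transition matrix of the post-MI model
#'
#' Builds the 7-state row-stochastic matrix for one cycle. The living
#' states face the cycle's effect-adjusted event probabilities: non-fatal
#' MI moves to the 1-year acute MI tunnel state, non-fatal ischemic
#' stroke to the acute IS tunnel, CV death and non-CV death to their
#' absorbing states. Residual mass returns to the state's "home": the
#' event-free state stays event-free, acute states settle into their
#' post-event states, post states persist (memoryless recurrence; the
#' current state is defined by the most recent event, so cross-over
#' events are permitted). Death rows are unit vectors.
#'
#' @param schedule An `event_schedule` from [build_schedule()].
#' @param effect A `treatment_effect` from [effect_for_arm()].
#' @param cycle Cycle index within the schedule.
#' @param application Effect application convention; see [apply_effect()].
#' @return A 7 x 7 stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(schedule, effect, cycle,
                                    application = "hazard") {
  if (cycle < 1 || cycle > nrow(schedule)) {
    stop("cycle ", cycle, " outside the schedule horizon", call. = FALSE)
  }
  m <- effect$multipliers
  row <- schedule[cycle, ]
  p <- c(
    ACUTE_MI = apply_effect(row$non_fatal_mi, m[["non_fatal_mi"]], application),
    ACUTE_IS = apply_effect(row$non_fatal_is, m[["non_fatal_is"]], application),
    CV_DEATH = apply_effect(row$cv_death, m[["cv_death"]], application),
    NONCV_DEATH = apply_effect(row$non_cv_death, m[["non_cv_death"]],
                               application)
  )
  if (sum(p) > 1) {
    stop("invalid schedule at cycle ", cycle,
         ": adjusted event probabilities sum above 1", call. = FALSE)
  }
  states <- state_names()
  M <- matrix(0, 7, 7, dimnames = list(states, states))
  home <- c(EVENT_FREE = "EVENT_FREE", ACUTE_MI = "POST_MI",
            POST_MI = "POST_MI", ACUTE_IS = "POST_IS", POST_IS = "POST_IS")
  for (s in names(home)) {
    M[s, names(p)] <- p
    M[s, home[[s]]] <- M[s, home[[s]]] + (1 - sum(p))
  }
  M["CV_DEATH", "CV_DEATH"] <- 1
  M["NONCV_DEATH", "NONCV_DEATH"] <- 1
  M
}

# State reward table derived from the config; the weighted fatal-event
# cost is carried either as an annual reward on the CV-death state
# (default, matching the published cost totals) or as a one-time entry
# reward.
config_states <- function(config) {
  nm <- state_names()
  annual <- vapply(nm, function(s) config$states[[s]]$annual_cost, 0)
  util <- vapply(nm, function(s) config$states[[s]]$utility, 0)
  entry <- stats::setNames(numeric(7), nm)
  if (config$model$cv_death_cost == "entry") {
    entry["CV_DEATH"] <- annual[["CV_DEATH"]]
    annual["CV_DEATH"] <- 0
  }
  data.frame(name = nm, annual_cost = annual, transition_cost = entry,
             utility = util, alive = nm %in% alive_states(),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run one strategy arm through the full deterministic pipeline
#'
#' Builds the event-rate schedule, the arm's treatment effect and the
#' per-cycle transition matrices, propagates the cohort from the
#' event-free state, and accumulates discounted outcomes.
#'
#' @param config A `cea_config`.
#' @param strategy Strategy name (`"statin"`, `"alirocumab"`,
#'   `"ezetimibe"`).
#' @param mode Efficacy hypothesis, `"hr_clinical"` or `"rr_ldl"`.
#' @param price `"base"` uses the strategy's configured `drug_cost`
#'   (the discounted net price for alirocumab); `"full"` uses
#'   `drug_cost_full` where defined.
#' @param drug_cost Explicit annual price override (used by the
#'   value-based price solver); when given, `price` is ignored.
#' @param all_cause,effect_override Passed to [effect_for_arm()].
#' @param keep_trace Attach the cohort trace as attribute `"trace"`.
#' @return An `arm_outcome`.
#' @export
#' @examples
#' cfg <- base_case_config()
#' run_strategy(cfg, "statin")
run_strategy <- function(config, strategy, mode = "hr_clinical",
                         price = c("base", "full"), drug_cost = NULL,
                         all_cause = FALSE, effect_override = NULL,
                         keep_trace = FALSE) {
  price <- match.arg(price)
  spec <- config$strategies[[strategy]]
  if (is.null(spec)) stop("unknown strategy '", strategy, "'", call. = FALSE)
  if (is.null(drug_cost)) {
    drug_cost <- if (price == "full") {
      spec$drug_cost_full %||% spec$drug_cost
    } else {
      spec$drug_cost
    }
  }
  schedule <- build_schedule(config)
  effect <- effect_for_arm(config, strategy, mode, all_cause = all_cause,
                           override = effect_override)
  application <- config$model$effect_application
  init <- stats::setNames(c(1, rep(0, 6)), state_names())
  trace <- run_cohort(
    function(t) build_transition_matrix(schedule, effect, t, application),
    init, nrow(schedule))
  out <- accumulate_outcomes(
    trace, config_states(config), config$model$discount_rate,
    drug_cost = drug_cost,
    utility_penalty = spec$utility_penalty %||% 0,
    drug_accrual = config$model$drug_cost_accrual)
  if (keep_trace) attr(out, "trace") <- trace
  out
}

#' Export a cohort trace as a per-cycle table
#'
#' One row per cycle with state-occupancy, half-cycle-corrected weights
#' and the cycle's discount factor, suitable for delimited output.
#'
#' @param trace A `cohort_trace`.
#' @param discount_rate Annual discount rate for the factor column.
#' @return A data.frame with `cycle`, occupancy columns (cycle start),
#'   `hcc_` weight columns and `discount` factor.
#' @export
trace_table <- function(trace, discount_rate = 0.05) {
  h <- nrow(trace$occupancy) - 1L
  w <- half_cycle_correct(trace)
  occ <- trace$occupancy[seq_len(h), , drop = FALSE]
  colnames(w) <- paste0("hcc_", colnames(w))
  data.frame(cycle = seq_len(h), occ, w,
             discount = discount_factor(discount_rate, seq_len(h)),
             check.names = FALSE)
}

#' Deterministic base-case cost-effectiveness table
#'
#' Runs the reference and add-on strategies under both efficacy
#' hypotheses and both price settings, computing total and incremental
#' discounted costs and QALYs, ICERs and the value-based price (which is
#' independent of the price setting used to start the solve).
#'
#' @param config A `cea_config`.
#' @param strategy Add-on strategy compared against `comparator`.
#' @param comparator Reference strategy.
#' @param modes Efficacy hypotheses to evaluate.
#' @param prices Price settings to evaluate.
#' @return A data.frame in results-table shape (class
#'   `cea_table`): one block of two rows (reference, add-on) per
#'   mode x price combination, with columns `mode`, `price`, `strategy`,
#'   `cost`, `inc_cost`, `qaly`, `inc_qaly`, `icer`, `vbp`.
#' @export
#' @examples
#' \donttest{
#' run_base_case(base_case_config())
#' }
run_base_case <- function(config, strategy = "alirocumab",
                          comparator = "statin",
                          modes = c("hr_clinical", "rr_ldl"),
                          prices = c("base", "full")) {
  rows <- list()
  for (mode in modes) {
    ref <- run_strategy(config, comparator, mode = mode)
    vbp <- value_based_price(
      function(p) cea_compare(
        ref, run_strategy(config, strategy, mode = mode, drug_cost = p)),
      wtp = config$threshold$wtp)
    for (price in prices) {
      arm <- run_strategy(config, strategy, mode = mode, price = price)
      res <- cea_compare(ref, arm)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, price = price,
        strategy = c(comparator, strategy),
        cost = c(ref$total_cost, arm$total_cost),
        inc_cost = c(NA, res$delta_cost),
        qaly = c(ref$total_qaly, arm$total_qaly),
        inc_qaly = c(NA, res$delta_qaly),
        icer = c(NA, res$icer),
        vbp = c(NA, vbp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cea_table", "data.frame")
  out
}
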