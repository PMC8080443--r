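#' Build the age-escalated annual event-rate schedule
#'
#' Expands first-year event probabilities into a per-cycle schedule over
#' the model horizon. Rates are piecewise-constant within 5-year blocks
#' of attained age and are multiplied by one growth factor per completed
#' block past `reference_age`, emulating event risk that grows in line
#' with age-specific natural mortality. The last listed growth factor is
#' recycled for ages beyond the listed blocks (long horizons, old
#' starting ages). Subgroup `rate_multipliers` scale each endpoint.
#'
#' @param config A `cea_config`.
#' @param horizon Number of annual cycles; defaults to `model.horizon`.
#' @param starting_age Cohort age at entry; defaults to
#'   `model.starting_age`. Escalation tracks attained age, so an older
#'   starting cohort enters at already-escalated rates.
#' @return A data.frame (class `event_schedule`) with columns `cycle`,
#'   `age`, and the four annual transition probabilities `non_fatal_mi`,
#'   `non_fatal_is`, `cv_death`, `non_cv_death`.
#' @export
#' @examples
#' sched <- build_schedule(base_case_config())
#' sched[1, ]  # first-year probabilities 0.017 / 0.009 / 0.022 / 0.009
build_schedule <- function(config, horizon = NULL, starting_age = NULL) {
  p <- config$population
  horizon <- horizon %||% config$model$horizon
  starting_age <- starting_age %||% config$model$starting_age
  cycles <- seq_len(horizon)
  age <- starting_age + cycles - 1L
  block <- pmax(0L, (age - p$reference_age) %/% p$block_years)

  out <- data.frame(cycle = cycles, age = age)
  for (ep in transition_endpoints()) {
    gf <- as.numeric(p$growth_factors[[ep]])
    mult <- p$rate_multipliers[[ep]] %||% 1
    # cumulative product of completed-block factors, recycling the last
    cum <- cumprod(gf[pmin(seq_len(max(block, 1L)), length(gf))])
    escal <- c(1, cum)[block + 1L]
    out[[ep]] <- p$base_rates[[ep]] * escal * mult
  }

  rates <- as.matrix(out[transition_endpoints()])
  if (any(rates < 0 | rates > 1)) {
    bad <- which(rowSums(rates < 0 | rates > 1) > 0)[1]
    stop("infeasible event-rate schedule: probability outside [0, 1] at ",
         "cycle ", bad, call. = FALSE)
  }
  if (any(rowSums(rates) > 1)) {
    bad <- which(rowSums(rates) > 1)[1]
    stop("infeasible event-rate schedule: event probabilities sum above 1 ",
         "at cycle ", bad, call. = FALSE)
  }
  class(out) <- c("event_schedule", "data.frame")
  out
}

#' Generate a randomized toy Markov model for property testing
#'
#' Draws a small self-contained cohort model (transition matrices, state
#' rewards, and one or more drug strategies) whose structure always
#' satisfies the engine invariants: rows are stochastic, the final state
#' is absorbing with zero reward, utilities lie in \[0, 1\] and costs are
#' non-negative. Used to cross-check the cohort engine against
#' per-individual microsimulation and to exercise the incremental
#' analysis on models with no special structure.
#'
#' @param n_states Number of states (>= 2); the last state is absorbing
#'   ("dead").
#' @param horizon Number of cycles.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param p_event_max Upper bound of the uniform range for off-diagonal
#'   transition mass per row.
#' @param cost_max,utility_max Upper bounds for state rewards.
#' @return A list (class `toy_model`) with elements `matrices` (list of
#'   per-cycle transition matrices), `init`, `horizon`, `states`
#'   (reward data.frame), and `strategies` (named annual drug costs).
#' @export
generate_toy_model <- function(n_states = 3, horizon = 5, seed = 1,
                               p_event_max = 0.4, cost_max = 50000,
                               utility_max = 1) {
  stopifnot(n_states >= 2, horizon >= 1, p_event_max > 0, p_event_max <= 1)
  set.seed(seed)
  labels <- c(paste0("S", seq_len(n_states - 1)), "DEAD")
  matrices <- lapply(seq_len(horizon), function(t) {
    M <- matrix(0, n_states, n_states, dimnames = list(labels, labels))
    for (s in seq_len(n_states - 1)) {
      off <- stats::runif(n_states - 1, 0, p_event_max / (n_states - 1))
      M[s, -s] <- off
      M[s, s] <- 1 - sum(off)
    }
    M[n_states, n_states] <- 1
    M
  })
  states <- data.frame(
    name = labels,
    annual_cost = c(stats::runif(n_states - 1, 0, cost_max), 0),
    transition_cost = c(rep(0, n_states - 1),
                        stats::runif(1, 0, cost_max)),
    utility = c(stats::runif(n_states - 1, 0.2, utility_max), 0),
    alive = c(rep(TRUE, n_states - 1), FALSE),
    stringsAsFactors = FALSE
  )
  structure(
    list(matrices = matrices,
         init = c(1, rep(0, n_states - 1)),
         horizon = horizon,
         states = states,
         strategies = c(control = 0,
                        treated = stats::runif(1, 0, 40000))),
    class = "toy_model")
}

#' Run one arm of a toy model through the cohort engine
#'
#' @param toy A `toy_model` from [generate_toy_model()].
#' @param drug_cost Annual drug cost applied to the alive states.
#' @param discount_rate Annual discount rate.
#' @return An `arm_outcome`, as from [accumulate_outcomes()].
#' @export
run_toy_model <- function(toy, drug_cost = 0, discount_rate = 0) {
  trace <- run_cohort(function(t) toy$matrices[[t]], toy$init, toy$horizon)
  accumulate_outcomes(trace, toy$states, discount_rate,
                      drug_cost = drug_cost, drug_accrual = "alive")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
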