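#' Fit a log-normal distribution from a point estimate and 95% CI
#'
#' Standard CI-matching fit for hazard ratios, relative risks and cost
#' parameters: the default anchors the sampled median at the point
#' estimate (`meanlog = log(point)`) with
#' `sdlog = (log(high) - log(low)) / (2 * 1.959964)`. The alternative
#' `anchor = "mean"` shifts the location so the sampled mean equals the
#' point estimate.
#'
#' @param point Point estimate (> 0).
#' @param low,high 95% interval bounds (0 < low <= point <= high).
#' @param anchor `"median"` (default) or `"mean"`.
#' @return A `param_dist` list with `family = "lognormal"`, `meanlog`,
#'   `sdlog`.
#' @export
#' @examples
#' fit_lognormal(0.86, 0.77, 0.96)  # meanlog -0.1508, sdlog 0.0563
fit_lognormal <- function(point, low, high, anchor = c("median", "mean")) {
  anchor <- match.arg(anchor)
  if (low <= 0 || low > point || point > high) {
    stop("need 0 < low <= point <= high", call. = FALSE)
  }
  sdlog <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
  meanlog <- switch(anchor,
                    median = log(point),
                    mean = log(point) - sdlog^2 / 2)
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 point = point),
            class = "param_dist")
}

#' Fit a beta distribution from a mean and 95% CI
#'
#' Method-of-moments fit for utility weights: the standard deviation is
#' taken as `(high - low) / (2 * 1.959964)` and the shape parameters
#' solve the mean/variance equations. A shifted-and-scaled support
#' accommodates parameters outside \[0, 1\], such as the injection-site
#' disutility, which is fitted as a beta on its reflected range.
#'
#' @param mean Target mean, strictly inside `support`.
#' @param low,high 95% interval bounds giving the SD.
#' @param support Interval carrying the distribution (default \[0, 1\]).
#' @return A `param_dist` list with `family = "beta"`, `shape1`,
#'   `shape2`, `support`.
#' @export
#' @examples
#' fit_beta(0.824, 0.800, 0.848)  # shapes ~ (796.2, 170.1)
fit_beta <- function(mean, low, high, support = c(0, 1)) {
  a <- support[1]; b <- support[2]
  if (mean <= a || mean >= b) {
    stop("mean must lie strictly inside the support", call. = FALSE)
  }
  m <- (mean - a) / (b - a)
  s <- (high - low) / (2 * stats::qnorm(0.975)) / (b - a)
  if (s^2 >= m * (1 - m)) {
    stop("implied variance is infeasible for a beta distribution",
         call. = FALSE)
  }
  k <- m * (1 - m) / s^2 - 1
  structure(list(family = "beta", shape1 = m * k, shape2 = (1 - m) * k,
                 support = support, point = mean),
            class = "param_dist")
}

fit_fixed <- function(point) {
  structure(list(family = "fixed", point = point), class = "param_dist")
}

#' Draw samples from a fitted parameter distribution
#'
#' @param fit A `param_dist` from [fit_lognormal()], [fit_beta()] or an
#'   internal fixed fit.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(fit, n) {
  switch(fit$family,
    lognormal = stats::rlnorm(n, fit$meanlog, fit$sdlog),
    beta = {
      a <- fit$support[1]; b <- fit$support[2]
      a + (b - a) * stats::rbeta(n, fit$shape1, fit$shape2)
    },
    fixed = rep(fit$point, n),
    stop("unknown distribution family '", fit$family, "'", call. = FALSE))
}

#' Table of sampled parameters and their fitted distributions
#'
#' Enumerates every uncertain input of the probabilistic analysis:
#' per-state annual costs (log-normal, +/- 25% ranges), utility weights
#' (beta from 95% CIs), the injection-site disutility (beta on its
#' reflected range) and the per-endpoint treatment effects of each
#' sampled strategy under the chosen efficacy hypothesis (log-normal
#' from 95% CIs). Event-rate probabilities are deliberately not sampled;
#' they vary only through age escalation.
#'
#' @param config A `cea_config`.
#' @param mode Efficacy hypothesis for the effect parameters.
#' @param strategies Strategies whose effects are sampled.
#' @param anchor Log-normal anchoring convention, see [fit_lognormal()].
#' @return A data.frame with columns `name` (dotted config path),
#'   `family`, `point`, `low`, `high`, and a list-column `fit` of
#'   `param_dist` objects.
#' @export
psa_parameters <- function(config, mode = "hr_clinical",
                           strategies = c("statin", "alirocumab"),
                           anchor = "median") {
  rows <- list()
  add <- function(name, family, point, low, high, fit) {
    rows[[length(rows) + 1L]] <<- list(name = name, family = family,
                                       point = point, low = low,
                                       high = high, fit = fit)
  }
  cost_states <- c(alive_states(), "CV_DEATH")
  for (s in cost_states) {
    st <- config$states[[s]]
    if (is.null(st$cost_range)) next
    add(paste0("states.", s, ".annual_cost"), "lognormal",
        st$annual_cost, st$cost_range[1], st$cost_range[2],
        fit_lognormal(st$annual_cost, st$cost_range[1], st$cost_range[2],
                      anchor = anchor))
  }
  for (s in alive_states()) {
    st <- config$states[[s]]
    if (is.null(st$utility_range)) next
    add(paste0("states.", s, ".utility"), "beta",
        st$utility, st$utility_range[1], st$utility_range[2],
        fit_beta(st$utility, st$utility_range[1], st$utility_range[2]))
  }
  for (nm in strategies) {
    spec <- config$strategies[[nm]]
    if (!is.null(spec$utility_penalty_range)) {
      rng <- spec$utility_penalty_range
      add(paste0("strategies.", nm, ".utility_penalty"), "beta",
          spec$utility_penalty, rng[1], rng[2],
          fit_beta(spec$utility_penalty, rng[1], rng[2],
                   support = c(rng[1], rng[2])))
    }
    if (identical(spec$effect, "none")) next
    block <- config$effects[[spec$effect]][[mode]]
    for (ep in c("non_fatal_mi", "non_fatal_is", "cv_death")) {
      entry <- block[[ep]]
      if (is.null(entry) || is.null(entry$ci)) next
      add(paste0("effects.", spec$effect, ".", mode, ".", ep, ".point"),
          "lognormal", entry$point, entry$ci[1], entry$ci[2],
          fit_lognormal(entry$point, entry$ci[1], entry$ci[2],
                        anchor = anchor))
    }
  }
  out <- data.frame(
    name = vapply(rows, `[[`, "", "name"),
    family = vapply(rows, `[[`, "", "family"),
    point = vapply(rows, `[[`, 0, "point"),
    low = vapply(rows, `[[`, 0, "low"),
    high = vapply(rows, `[[`, 0, "high"),
    stringsAsFactors = FALSE)
  out$fit <- lapply(rows, `[[`, "fit")
  out
}

#' One-way deterministic sensitivity sweep of a single parameter
#'
#' Re-runs the deterministic pairwise analysis with one input set to
#' each endpoint of its plausible range, all other inputs at base-case
#' values (exactly two full model evaluations).
#'
#' @param config A `cea_config`.
#' @param path Dotted configuration path of the parameter.
#' @param low,high Range endpoints.
#' @param mode,price,strategy,comparator Passed to [run_strategy()].
#' @return A one-row data.frame: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`.
#' @export
one_way_sweep <- function(config, path, low, high, mode = "hr_clinical",
                          price = "base", strategy = "alirocumab",
                          comparator = "statin") {
  eval_at <- function(value) {
    cfg <- set_config_value(config, path, value)
    ref <- run_strategy(cfg, comparator, mode = mode)
    arm <- run_strategy(cfg, strategy, mode = mode, price = price)
    cea_compare(ref, arm)$icer
  }
  icer_low <- eval_at(low)
  icer_high <- eval_at(high)
  data.frame(parameter = path, low = low, high = high,
             icer_low = icer_low, icer_high = icer_high,
             span = abs(icer_high - icer_low),
             stringsAsFactors = FALSE)
}

#' Tornado analysis over the economic inputs
#'
#' Sweeps every cost, utility and disutility parameter across its
#' declared range and ranks parameters by the absolute ICER span. The
#' treatment-effect parameters are excluded by default: the two
#' efficacy hypotheses are explored as structural modes and through the
#' probabilistic analysis; set `include_effects = TRUE` to sweep their
#' CIs as well. Endpoint ICERs are reported without interpolation (they
#' may be non-monotone in utility parameters).
#'
#' @inheritParams one_way_sweep
#' @param include_effects Also sweep the per-endpoint effect CIs.
#' @return A data.frame of [one_way_sweep()] rows sorted by `span`
#'   descending (class `tornado`).
#' @export
tornado <- function(config, mode = "hr_clinical", price = "base",
                    strategy = "alirocumab", comparator = "statin",
                    include_effects = FALSE) {
  params <- psa_parameters(config, mode = mode,
                           strategies = c(comparator, strategy))
  if (!include_effects) {
    params <- params[!startsWith(params$name, "effects."), ]
  }
  rows <- lapply(seq_len(nrow(params)), function(i) {
    one_way_sweep(config, params$name[i], params$low[i], params$high[i],
                  mode = mode, price = price, strategy = strategy,
                  comparator = comparator)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` independent joint parameter sets from the fitted
#' distributions (no correlation structure) and evaluates the full
#' deterministic model for every strategy at each draw. The event-rate
#' schedule is never sampled, so the reference-arm cohort trace is
#' computed once and only re-costed per draw; treated-arm traces are
#' rebuilt whenever their effect parameters are sampled. The entire
#' analysis is a pure function of (config, seed, n_draws).
#'
#' @param config A `cea_config`.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed.
#' @param mode Efficacy hypothesis.
#' @param price Price setting for drug costs.
#' @param strategies Strategies evaluated per draw.
#' @return A `psa_result`: list with `params` (n x p matrix of sampled
#'   values), `costs` and `qalys` (n x strategy matrices), plus the
#'   settings used.
#' @export
run_psa <- function(config, n_draws = 1000, seed = 1,
                    mode = "hr_clinical", price = "base",
                    strategies = c("statin", "alirocumab")) {
  stopifnot(n_draws >= 1)
  par_tab <- psa_parameters(config, mode = mode, strategies = strategies)
  set.seed(seed)
  draws <- vapply(par_tab$fit, sample_dist, numeric(n_draws), n = n_draws)
  draws <- matrix(draws, nrow = n_draws,
                  dimnames = list(NULL, par_tab$name))

  schedule <- build_schedule(config)
  application <- config$model$effect_application
  init <- stats::setNames(c(1, rep(0, 6)), state_names())
  run_trace <- function(effect) {
    run_cohort(function(t) build_transition_matrix(schedule, effect, t,
                                                   application),
               init, nrow(schedule))
  }
  # Trace reuse: arms whose effect parameters are not sampled keep a
  # fixed trace across draws.
  effect_paths <- lapply(strategies, function(nm) {
    grep(paste0("^effects\\.", config$strategies[[nm]]$effect, "\\."),
         par_tab$name, value = TRUE)
  })
  names(effect_paths) <- strategies
  base_traces <- lapply(strategies, function(nm) {
    if (length(effect_paths[[nm]]) == 0L) {
      run_trace(effect_for_arm(config, nm, mode))
    } else NULL
  })
  names(base_traces) <- strategies

  costs <- matrix(NA_real_, n_draws, length(strategies),
                  dimnames = list(NULL, strategies))
  qalys <- costs
  for (i in seq_len(n_draws)) {
    cfg <- config
    for (j in seq_len(ncol(draws))) {
      cfg <- set_config_value(cfg, colnames(draws)[j], draws[i, j])
    }
    states <- config_states(cfg)
    for (nm in strategies) {
      spec <- cfg$strategies[[nm]]
      trace <- base_traces[[nm]] %||%
        run_trace(effect_for_arm(cfg, nm, mode))
      drug_cost <- if (price == "full") {
        spec$drug_cost_full %||% spec$drug_cost
      } else spec$drug_cost
      out <- accumulate_outcomes(trace, states, cfg$model$discount_rate,
                                 drug_cost = drug_cost,
                                 utility_penalty = spec$utility_penalty %||% 0,
                                 drug_accrual = cfg$model$drug_cost_accrual)
      costs[i, nm] <- out$total_cost
      qalys[i, nm] <- out$total_qaly
    }
  }
  structure(list(params = draws, costs = costs, qalys = qalys,
                 strategies = strategies, mode = mode, price = price,
                 seed = seed, n_draws = n_draws,
                 wtp = config$threshold$wtp),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curves
#'
#' For `type = "pairwise"`, the probability that each add-on strategy
#' has higher net monetary benefit than the comparator at each
#' willingness-to-pay value; for `type = "multi"`, the probability that
#' each strategy (comparator included) has the maximal net monetary
#' benefit, so probabilities sum to 1 across strategies at every
#' threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Vector of willingness-to-pay values (CNY/QALY);
#'   default 0 to 1,000,000 in 10,000-CNY steps.
#' @param type `"pairwise"` or `"multi"`.
#' @param comparator Reference strategy for pairwise curves.
#' @return A data.frame with `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1e6, by = 1e4),
                 type = c("pairwise", "multi"), comparator = "statin") {
  type <- match.arg(type)
  if (length(wtp_grid) == 0L) stop("empty wtp grid", call. = FALSE)
  rows <- lapply(wtp_grid, function(w) {
    nmb <- w * psa$qalys - psa$costs
    if (type == "pairwise") {
      others <- setdiff(psa$strategies, comparator)
      data.frame(wtp = w, strategy = others,
                 probability = vapply(others, function(s) {
                   mean(nmb[, s] > nmb[, comparator])
                 }, 0),
                 stringsAsFactors = FALSE)
    } else {
      best <- psa$strategies[max.col(nmb, ties.method = "first")]
      data.frame(wtp = w, strategy = psa$strategies,
                 probability = vapply(psa$strategies, function(s) {
                   mean(best == s)
                 }, 0),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Acceptability of a strategy at a single threshold
#'
#' Convenience wrapper: fraction of draws in which `strategy` has higher
#' net monetary benefit than `comparator` at `wtp`.
#'
#' @inheritParams ceac
#' @param wtp Willingness-to-pay threshold (defaults to the config value
#'   stored with the PSA).
#' @param strategy Add-on strategy.
#' @return Probability in \[0, 1\].
#' @export
acceptability <- function(psa, wtp = psa$wtp, strategy = "alirocumab",
                          comparator = "statin") {
  nmb <- wtp * psa$qalys - psa$costs
  mean(nmb[, strategy] > nmb[, comparator])
}

#' Summarise distribution fits against their source ranges
#'
#' For every sampled parameter of both efficacy hypotheses, draws `n`
#' values and reports the achieved central statistic (median for
#' log-normal, mean for beta) against the configured point value, and
#' the fraction of draws inside the printed range.
#'
#' @param config A `cea_config`.
#' @param n Draws per parameter.
#' @param seed Integer seed.
#' @return A data.frame with `name`, `family`, `point`, `achieved`,
#'   `rel_error`, `coverage`.
#' @export
check_distribution_fits <- function(config, n = 1e5, seed = 1) {
  tabs <- lapply(c("hr_clinical", "rr_ldl"), function(mode) {
    psa_parameters(config, mode = mode,
                   strategies = c("statin", "alirocumab"))
  })
  tab <- do.call(rbind, tabs)
  tab <- tab[!duplicated(tab$name), ]
  set.seed(seed)
  res <- lapply(seq_len(nrow(tab)), function(i) {
    x <- sample_dist(tab$fit[[i]], n)
    achieved <- if (tab$family[i] == "lognormal") stats::median(x) else mean(x)
    target <- tab$point[i]
    data.frame(name = tab$name[i], family = tab$family[i], point = target,
               achieved = achieved,
               rel_error = abs(achieved - target) /
                 max(abs(target), .Machine$double.eps),
               coverage = mean(x >= pmin(tab$low[i], tab$high[i]) &
                               x <= pmax(tab$low[i], tab$high[i])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
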