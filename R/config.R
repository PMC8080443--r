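#' Load the canonical base-case model configuration
#'
#' Reads the versioned base-case configuration shipped with the package:
#' first-year event probabilities of the post-MI cohort, age-escalation
#' growth factors, per-state costs and utilities, drug prices, treatment
#' effects under both efficacy hypotheses, and the willingness-to-pay
#' threshold (3 x 2019 per-capita GDP = 212,676 CNY/QALY).
#'
#' @return A nested list (class `cea_config`) validated by
#'   [validate_config()].
#' @export
#' @examples
#' cfg <- base_case_config()
#' cfg$threshold$wtp
base_case_config <- function() {
  path <- system.file("extdata", "base_case.yaml", package = "pcsk9cea",
                      mustWork = TRUE)
  read_config(path)
}

#' Read a model configuration from a YAML file
#'
#' @param path Path to a YAML configuration file with the same layout as
#'   the shipped `base_case.yaml`.
#' @return A validated `cea_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Write a model configuration to a YAML file
#'
#' @param config A `cea_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a model configuration
#'
#' Checks the structural and numerical invariants of a configuration:
#' probabilities in \[0, 1\] with feasible per-cycle sums, growth factors
#' >= 1, non-negative costs, utilities in \[-0.1, 1\] with zero utility
#' and (non-transition) reward coherence for death states, non-negative
#' drug prices and non-positive utility penalties, and a positive
#' willingness-to-pay threshold consistent with its GDP derivation when
#' one is given.
#'
#' @param config A configuration list.
#' @return The configuration with class `cea_config`, invisibly usable
#'   downstream; errors describe the offending field.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  for (block in c("model", "population", "states", "threshold",
                  "strategies", "effects")) {
    if (is.null(config[[block]])) {
      stop("configuration is missing the '", block, "' block", call. = FALSE)
    }
  }
  m <- config$model
  if (!is.numeric(m$horizon) || m$horizon < 1) {
    stop("model.horizon must be >= 1", call. = FALSE)
  }
  if (m$discount_rate < 0 || m$discount_rate > 0.2) {
    stop("model.discount_rate must lie in [0, 0.2]", call. = FALSE)
  }
  if (!m$drug_cost_accrual %in% c("fixed_horizon", "alive")) {
    stop("model.drug_cost_accrual must be 'fixed_horizon' or 'alive'",
         call. = FALSE)
  }
  if (!m$cv_death_cost %in% c("annual", "entry")) {
    stop("model.cv_death_cost must be 'annual' or 'entry'", call. = FALSE)
  }
  if (!m$effect_application %in% c("hazard", "probability")) {
    stop("model.effect_application must be 'hazard' or 'probability'",
         call. = FALSE)
  }

  p <- config$population
  rates <- unlist(p$base_rates[transition_endpoints()])
  if (length(rates) != 4L || anyNA(rates)) {
    stop("population.base_rates must give all four endpoints", call. = FALSE)
  }
  if (any(rates < 0 | rates > 1) || sum(rates) > 1) {
    stop("population.base_rates must be probabilities with sum <= 1",
         call. = FALSE)
  }
  for (ep in transition_endpoints()) {
    gf <- p$growth_factors[[ep]]
    if (is.null(gf) || any(gf < 1)) {
      stop("population.growth_factors.", ep, " must all be >= 1 ",
           "(event risk grows with age)", call. = FALSE)
    }
    mult <- p$rate_multipliers[[ep]]
    if (!is.null(mult) && mult < 0) {
      stop("population.rate_multipliers.", ep, " must be >= 0", call. = FALSE)
    }
  }

  for (s in state_names()) {
    st <- config$states[[s]]
    if (is.null(st)) stop("states.", s, " is missing", call. = FALSE)
    if (st$annual_cost < 0) {
      stop("states.", s, ".annual_cost must be >= 0", call. = FALSE)
    }
    if (st$utility < -0.1 || st$utility > 1) {
      stop("states.", s, ".utility must lie in [-0.1, 1]", call. = FALSE)
    }
  }
  if (config$states$NONCV_DEATH$annual_cost != 0 ||
      config$states$NONCV_DEATH$utility != 0 ||
      config$states$CV_DEATH$utility != 0) {
    stop("death states must have zero utility and NONCV_DEATH zero cost",
         call. = FALSE)
  }

  th <- config$threshold
  if (is.null(th$wtp) || th$wtp <= 0) {
    stop("threshold.wtp must be > 0", call. = FALSE)
  }
  if (!is.null(th$gdp_per_capita) && !is.null(th$multiplier)) {
    derived <- th$gdp_per_capita * th$multiplier
    if (abs(derived - th$wtp) > 0.5) {
      stop("threshold.wtp does not equal multiplier x gdp_per_capita",
           call. = FALSE)
    }
  }

  for (nm in names(config$strategies)) {
    st <- config$strategies[[nm]]
    if (st$drug_cost < 0) {
      stop("strategies.", nm, ".drug_cost must be >= 0", call. = FALSE)
    }
    if (!is.null(st$utility_penalty) && st$utility_penalty > 0) {
      stop("strategies.", nm, ".utility_penalty must be <= 0", call. = FALSE)
    }
    if (!identical(st$effect, "none") &&
        is.null(config$effects[[st$effect]])) {
      stop("strategies.", nm, " references unknown effect '", st$effect,
           "'", call. = FALSE)
    }
  }
  structure(config, class = c("cea_config", "list"))
}

#' Merge scenario overrides into a configuration
#'
#' Recursively merges a nested override list into a base configuration
#' (as used by [run_scenario()]) and re-validates the result.
#'
#' @param config Base `cea_config`.
#' @param overrides Nested named list mirroring the configuration layout;
#'   leaves replace the corresponding base values.
#' @return The merged, validated configuration.
#' @export
merge_config <- function(config, overrides) {
  if (length(overrides) == 0L) return(validate_config(config))
  merged <- utils::modifyList(unclass(config), overrides)
  validate_config(merged)
}

#' Set a single configuration value by dotted path
#'
#' Used by the one-way and probabilistic sensitivity machinery to perturb
#' one scalar input, e.g. `"states.ACUTE_MI.annual_cost"` or
#' `"effects.alirocumab.hr_clinical.non_fatal_mi.point"`.
#'
#' @param config A `cea_config`.
#' @param path Dotted parameter path.
#' @param value Replacement scalar.
#' @return The modified configuration (not re-validated; sensitivity
#'   sweeps may legitimately cross validation bounds such as HR > 1).
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  cfg <- unclass(config)
  ref <- cfg
  for (k in keys[-length(keys)]) {
    if (is.null(ref[[k]])) {
      stop("unknown configuration path: ", path, call. = FALSE)
    }
    ref <- ref[[k]]
  }
  if (is.null(ref[[keys[length(keys)]]])) {
    stop("unknown configuration path: ", path, call. = FALSE)
  }
  cfg[[keys]] <- value
  structure(cfg, class = c("cea_config", "list"))
}

#' Get a single configuration value by dotted path
#' @inheritParams set_config_value
#' @return The scalar stored at `path`.
#' @export
get_config_value <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- unclass(config)
  for (k in keys) {
    out <- out[[k]]
    if (is.null(out)) stop("unknown configuration path: ", path, call. = FALSE)
  }
  out
}

# Canonical orderings used throughout the engine.
state_names <- function() {
  c("EVENT_FREE", "ACUTE_MI", "POST_MI", "ACUTE_IS", "POST_IS",
    "CV_DEATH", "NONCV_DEATH")
}

transition_endpoints <- function() {
  c("non_fatal_mi", "non_fatal_is", "cv_death", "non_cv_death")
}

alive_states <- function() {
  c("EVENT_FREE", "ACUTE_MI", "POST_MI", "ACUTE_IS", "POST_IS")
}
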