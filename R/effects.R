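#' Relative risk from absolute LDL-C reduction
#'
#' Converts an absolute LDL-C reduction into a per-endpoint relative
#' risk by compounding the per-1-mmol/L risk relationship:
#' `rr = rr_per_mmol ^ delta_ldl`. This is the LDL-C-reduction efficacy
#' hypothesis, combining the drug's measured lipid-lowering with the
#' meta-analytic risk reduction per mmol/L.
#'
#' @param rr_per_mmol Relative risk per 1 mmol/L LDL-C reduction, in
#'   (0, 1]; may be a named vector (one entry per endpoint).
#' @param delta_ldl Absolute LDL-C reduction in mmol/L (>= 0).
#' @return Multiplier(s) in (0, 1], same shape as `rr_per_mmol`.
#' @export
#' @examples
#' rr_from_ldl(0.8, 2)  # 0.64
rr_from_ldl <- function(rr_per_mmol, delta_ldl) {
  if (delta_ldl < 0) stop("delta_ldl must be >= 0", call. = FALSE)
  if (any(rr_per_mmol <= 0 | rr_per_mmol > 1)) {
    stop("rr_per_mmol must lie in (0, 1]", call. = FALSE)
  }
  rr_per_mmol^delta_ldl
}

#' Treatment-effect multipliers for a strategy arm
#'
#' Builds the per-endpoint multiplicative effect set for one strategy
#' under a given efficacy hypothesis:
#' \itemize{
#'   \item the statin-alone reference arm always receives the null
#'     effect (all multipliers 1);
#'   \item `hr_clinical` uses the trial-follow-up hazard ratios on
#'     non-fatal MI, non-fatal ischemic stroke and CV death;
#'   \item `rr_ldl` uses relative risks derived from the LDL-C-reduction
#'     hypothesis;
#'   \item the all-cause-death variant (`all_cause = TRUE`) routes the
#'     trial's all-cause mortality effect to both death transitions
#'     (under `rr_ldl` the LDL-derived CV-death RR is applied to both);
#'   \item the ezetimibe comparator composes its clinical HRs for
#'     non-fatal events with the LDL-derived RR for CV death (its
#'     `rr_ldl` block, when absent, is derived entirely from
#'     `ldl_derivation`).
#' }
#' Non-CV death is unmodified by treatment except in the all-cause
#' variant.
#'
#' @param config A `cea_config`.
#' @param strategy Strategy name in `config$strategies`.
#' @param mode `"hr_clinical"`, `"rr_ldl"`, or `"none"`.
#' @param all_cause Apply the all-cause-death efficacy variant.
#' @param override Optional named multipliers replacing individual
#'   endpoints (scenario hook, e.g. subgroup-specific death effects).
#' @return A `treatment_effect`: list with `mode` and `multipliers`, a
#'   named vector over `non_fatal_mi`, `non_fatal_is`, `cv_death`,
#'   `non_cv_death`.
#' @export
#' @examples
#' cfg <- base_case_config()
#' effect_for_arm(cfg, "alirocumab", "hr_clinical")$multipliers
effect_for_arm <- function(config, strategy,
                           mode = c("hr_clinical", "rr_ldl", "none"),
                           all_cause = FALSE, override = NULL) {
  mode <- match.arg(mode)
  spec <- config$strategies[[strategy]]
  if (is.null(spec)) stop("unknown strategy '", strategy, "'", call. = FALSE)

  mult <- c(non_fatal_mi = 1, non_fatal_is = 1, cv_death = 1,
            non_cv_death = 1)
  if (!identical(spec$effect, "none") && mode != "none") {
    eff <- config$effects[[spec$effect]]
    if (is.null(eff)) {
      stop("strategy '", strategy, "' has no effect block", call. = FALSE)
    }
    block <- effect_block(eff, mode)
    for (ep in c("non_fatal_mi", "non_fatal_is", "cv_death")) {
      mult[ep] <- block[[ep]]$point
    }
    if (all_cause) {
      ac <- if (mode == "hr_clinical" && !is.null(eff$all_cause)) {
        eff$all_cause$point
      } else {
        mult["cv_death"]
      }
      mult["cv_death"] <- ac
      mult["non_cv_death"] <- ac
    }
  }
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(mult))
    if (length(bad)) {
      stop("unknown effect endpoints in override: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mult[names(override)] <- unlist(override)
  }
  if (any(mult <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
  structure(list(mode = if (identical(spec$effect, "none")) "none" else mode,
                 multipliers = mult),
            class = "treatment_effect")
}

# Resolve the per-endpoint {point, ci} block for a mode, deriving an
# rr_ldl block from the ldl_derivation layer when not stored directly,
# and filling a missing cv_death clinical HR from the LDL derivation
# (ezetimibe composition).
effect_block <- function(eff, mode) {
  derive <- function(ep) {
    d <- eff$ldl_derivation
    if (is.null(d)) {
      stop("effect has neither a '", mode, "' entry for ", ep,
           " nor an ldl_derivation layer", call. = FALSE)
    }
    list(point = rr_from_ldl(d$rr_per_mmol[[ep]], d$delta_ldl))
  }
  block <- eff[[mode]]
  out <- list()
  for (ep in c("non_fatal_mi", "non_fatal_is", "cv_death")) {
    out[[ep]] <- block[[ep]] %||% derive(ep)
  }
  out
}

#' Apply a multiplicative effect to an annual event probability
#'
#' Under the default `"hazard"` convention, trial hazard ratios and
#' relative risks multiply the underlying constant hazard, giving
#' `p' = 1 - (1 - p)^m` (proportional-hazards semantics). The
#' `"probability"` convention multiplies the probability directly
#' (`p' = m * p`), retained for structural sensitivity analysis.
#'
#' @param p Baseline annual probability (vector allowed).
#' @param m Positive multiplier.
#' @param application `"hazard"` or `"probability"`.
#' @return Adjusted probabilities.
#' @export
#' @examples
#' apply_effect(0.017, 0.86)  # 1 - (1 - 0.017)^0.86 = 0.01464
apply_effect <- function(p, m, application = c("hazard", "probability")) {
  application <- match.arg(application)
  if (any(m <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
  switch(application,
         hazard = 1 - (1 - p)^m,
         probability = m * p)
}
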