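#' Pairwise incremental cost-effectiveness
#'
#' Computes incremental cost, incremental QALYs and their ratio between
#' an add-on strategy and a reference arm, always on full-precision
#' values (never on rounded reports). When the QALY difference is zero
#' the ICER is undefined and only the dominance flag is set; a strategy
#' that saves money while gaining QALYs is `DOMINANT`, one that costs
#' more while losing QALYs is `DOMINATED`.
#'
#' @param reference `arm_outcome` of the reference strategy.
#' @param comparator `arm_outcome` of the add-on strategy.
#' @return A `cea_result`: list with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when undefined) and `dominance` (`"NONE"`, `"DOMINANT"`,
#'   `"DOMINATED"`).
#' @export
#' @examples
#' a <- structure(list(total_cost = 400705, total_qaly = 7.22),
#'                class = "arm_outcome")
#' b <- structure(list(total_cost = 500705, total_qaly = 7.72),
#'                class = "arm_outcome")
#' cea_compare(a, b)$icer  # 200,000 CNY/QALY
cea_compare <- function(reference, comparator) {
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qaly - reference$total_qaly
  dominance <- if (dc < 0 && dq > 0) "DOMINANT"
               else if (dc > 0 && dq < 0) "DOMINATED"
               else "NONE"
  icer <- if (dq != 0) dc / dq else NA_real_
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dominance),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("incremental cost %.0f CNY | incremental QALY %.4f | ",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icer)) {
    cat("ICER undefined |")
  } else {
    cat(sprintf("ICER %.0f CNY/QALY |", x$icer))
  }
  cat(" dominance", x$dominance, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp x QALYs - cost`; the strategy with maximal net monetary benefit
#' at a given willingness-to-pay is optimal at that threshold.
#'
#' @param outcome An `arm_outcome` (or any list with `total_cost`,
#'   `total_qaly`).
#' @param wtp Willingness-to-pay threshold, CNY per QALY (>= 0).
#' @return Net monetary benefit in CNY.
#' @export
nmb <- function(outcome, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * outcome$total_qaly - outcome$total_cost
}

#' Solve the value-based price against a willingness-to-pay threshold
#'
#' Finds the annual drug price at which the incremental
#' cost-effectiveness ratio equals the threshold, by bisection on the
#' price axis. The ICER must be increasing in price over the bracket
#' (asserted by evaluating both endpoints); because total cost is linear
#' in price while QALYs are price-invariant, the solution is independent
#' of the price setting used elsewhere in the analysis.
#'
#' @param evaluate Function of an annual price returning a
#'   `cea_result` for the add-on arm at that price versus the reference.
#' @param wtp Willingness-to-pay threshold, CNY per QALY.
#' @param bracket Price interval searched, CNY/year.
#' @param tol Absolute price tolerance, CNY (default 1).
#' @return Annual price in CNY at which the ICER meets `wtp` within
#'   `tol`.
#' @export
value_based_price <- function(evaluate, wtp, bracket = c(0, 2e5), tol = 1) {
  f <- function(p) {
    res <- evaluate(p)
    if (res$delta_qaly <= 0) {
      stop("value-based price undefined: add-on arm gains no QALYs",
           call. = FALSE)
    }
    res$delta_cost - wtp * res$delta_qaly
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > fhi) {
    stop("ICER is not increasing in price over the bracket", call. = FALSE)
  }
  if (flo > 0 || fhi < 0) {
    stop("willingness-to-pay threshold unattainable within the price ",
         "bracket [", lo, ", ", hi, "]", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Percent price reduction to a target price
#'
#' @param full_price Reference (full list) annual price, > 0.
#' @param target_price Target annual price, >= 0.
#' @return Reduction in percent, rounded to the nearest integer.
#' @export
#' @examples
#' percent_price_reduction(51532, 6071)  # 88
percent_price_reduction <- function(full_price, target_price) {
  if (full_price <= 0 || target_price < 0) {
    stop("prices must be positive", call. = FALSE)
  }
  round(100 * (full_price - target_price) / full_price)
}
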