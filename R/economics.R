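# Rewards, discounting, incremental cost-effectiveness and price solving.

#' Annual ARIA monitoring cost from MRI unit cost and event rate
#'
#' Management of one ARIA (amyloid-related imaging abnormality) event
#' requires on average three additional MRI scans, so the expected annual
#' monitoring cost is `3 * mri_unit_cost * aria_rate`.
#'
#' @param mri_unit_cost Unit price of one MRI scan, US$.
#' @param aria_rate Annual probability of an ARIA event.
#' @return Expected annual ARIA cost, US$.
#' @export
#' @examples
#' aria_annual_cost(344.04, 0.15)  # ~154.82
aria_annual_cost <- function(mri_unit_cost, aria_rate) {
  stopifnot(mri_unit_cost >= 0, aria_rate >= 0)
  3 * mri_unit_cost * aria_rate
}

#' Discount factor for a cycle
#'
#' `1 / (1 + rate)^cycle`; cycle 0 is undiscounted.
#'
#' @param rate Annual discount rate (fraction), >= 0.
#' @param cycle Cycle index (vectorized).
#' @return Dimensionless discount factor.
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0)
  1 / (1 + rate)^cycle
}

drug_price_at <- function(schedule, cycle) {
  if (nrow(schedule) == 0) return(rep(0, length(cycle)))
  if (any(cycle < schedule$from_cycle[1])) {
    stop("cycle outside drug price schedule coverage", call. = FALSE)
  }
  idx <- findInterval(cycle, schedule$from_cycle)
  schedule$price[idx]
}

#' Undiscounted cost of one cycle
#'
#' Drug, administration and ARIA costs accrue on the treated fraction of
#' the cohort; outpatient and inpatient costs accrue on the alive fraction.
#' For a strategy without any drug cost (the reference arm), the ARIA
#' monitoring cost is an always-on annual cost on the alive fraction and no
#' administration cost is charged.
#'
#' @param params An `ad_parameters` object.
#' @param strategy A `strategy_spec`.
#' @param occupancy Named numeric vector of state occupancy for the cycle.
#' @param on_treatment Treated fraction for the cycle.
#' @param cycle Cycle index (0-based), used to look up the drug price.
#' @return Cost in US$ for this cycle, undiscounted.
#' @export
#' @examples
#' p <- ad_parameters()
#' occ <- c(MCI = 1, MILD = 0, MODERATE = 0, SEVERE = 0, DEATH = 0)
#' cycle_cost(p, p$strategies$aducanumab, occ, 1, 0)
cycle_cost <- function(params, strategy, occupancy, on_treatment, cycle) {
  alive <- sum(occupancy[alive_states()])
  care <- (params$costs$outpatient + params$costs$inpatient) * alive
  if (strategy_has_drug(strategy)) {
    drug <- drug_price_at(strategy$drug_price_schedule, cycle)
    care + (drug + strategy$admin_annual + strategy$aria_annual) * on_treatment
  } else {
    care + strategy$aria_annual * alive
  }
}

#' Discounted accumulation of life-years, QALYs and costs
#'
#' Attaches rewards to the start-of-cycle occupancy of a trace and
#' accumulates them with per-cycle discounting: life-years are the alive
#' fraction, QALYs weight each state by its utility (death contributes 0),
#' and costs follow [cycle_cost()]. With `half_cycle = TRUE` the first and
#' last cycles receive half weight; the base case leaves this off.
#'
#' @param trace A `cea_trace` from [simulate_cohort()].
#' @param params An `ad_parameters` object.
#' @param strategy The `strategy_spec` that produced the trace.
#' @param half_cycle Apply a half-cycle correction?
#' @return An object of class `"econ_result"`: discounted `ly`, `qaly`,
#'   `cost` and their undiscounted counterparts, plus the discount rate
#'   used.
#' @export
accumulate_outcomes <- function(trace, params, strategy, half_cycle = FALSE) {
  n <- nrow(trace$occupancy)
  rate <- strategy$discount_rate %||% params$discount_rate
  df <- discount_factor(rate, seq_len(n) - 1)
  w <- rep(1, n)
  if (half_cycle && n > 1) {
    w[1] <- 0.5
    w[n] <- 0.5
  }
  alive <- rowSums(trace$occupancy[, alive_states(), drop = FALSE])
  u <- c(params$utilities[alive_states()], DEATH = 0)
  qaly_t <- as.vector(trace$occupancy[, names(u), drop = FALSE] %*% u)
  cost_t <- vapply(seq_len(n), function(i) {
    cycle_cost(params, strategy, trace$occupancy[i, ], trace$on_treatment[i], i - 1L)
  }, numeric(1))

  structure(list(
    strategy = strategy$name,
    ly = sum(alive * w * df),
    qaly = sum(qaly_t * w * df),
    cost = sum(cost_t * w * df),
    ly_undisc = sum(alive * w),
    qaly_undisc = sum(qaly_t * w),
    cost_undisc = sum(cost_t * w),
    discount_rate = rate,
    cycles = n
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("Strategy '%s' (%d cycles, discount %.1f%%)\n", x$strategy,
              x$cycles, 100 * x$discount_rate))
  cat(sprintf("  LY   %8.4f (undiscounted %8.4f)\n", x$ly, x$ly_undisc))
  cat(sprintf("  QALY %8.4f (undiscounted %8.4f)\n", x$qaly, x$qaly_undisc))
  cat(sprintf("  cost %12.2f (undiscounted %12.2f)\n", x$cost, x$cost_undisc))
  invisible(x)
}

icer_value <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) return(NA_real_)
  delta_cost / delta_effect
}

dominance_label <- function(delta_cost, delta_qaly) {
  if (delta_cost > 0 && delta_qaly < 0) return("dominated")
  if (delta_cost < 0 && delta_qaly > 0) return("dominant")
  if (delta_qaly == 0 && delta_cost != 0) return("undefined")
  ""
}

#' Pairwise incremental cost-effectiveness analysis
#'
#' Computes cost, life-year and QALY deltas (from unrounded accumulations)
#' for each requested (intervention, reference) pair, the ICER per QALY and
#' per life-year, a dominance label ("dominated" when the intervention
#' costs more and yields fewer QALYs, "dominant" for the reverse,
#' "undefined" when the QALY delta is zero with a non-zero cost delta), and
#' a cost-effectiveness flag at the willingness-to-pay threshold.
#'
#' @param results Named list of `econ_result` objects.
#' @param pairs List of character pairs `c(intervention, reference)`.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @return Data frame of class `"cea_comparison"`.
#' @export
incremental_analysis <- function(results, pairs, wtp = 150000) {
  rows <- lapply(pairs, function(pr) {
    a <- results[[pr[1]]]
    b <- results[[pr[2]]]
    if (is.null(a) || is.null(b)) {
      missing <- pr[c(is.null(a), is.null(b))]
      stop("strategy '", missing[1], "' not found in results", call. = FALSE)
    }
    dc <- a$cost - b$cost
    dly <- a$ly - b$ly
    dq <- a$qaly - b$qaly
    lab <- dominance_label(dc, dq)
    iq <- icer_value(dc, dq)
    data.frame(
      intervention = pr[1], reference = pr[2],
      delta_cost = dc, delta_ly = dly, delta_qaly = dq,
      icer_per_ly = icer_value(dc, dly),
      icer_per_qaly = iq,
      dominance = lab,
      cost_effective = identical(lab, "dominant") ||
        (dq > 0 && !is.na(iq) && iq < wtp),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_comparison", "data.frame")
  out
}

#' Annual drug price meeting a willingness-to-pay threshold
#'
#' Drug price enters the discounted cost linearly and leaves effects
#' unchanged, so the price at which the intervention's ICER against a
#' reference equals `wtp` has a closed form. The result is the flat annual
#' price (replacing the strategy's whole price schedule) that attains the
#' threshold.
#'
#' @param params An `ad_parameters` object.
#' @param strategy Name of the priced strategy.
#' @param reference Name of the comparator strategy.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @param hr_method,half_cycle Model configuration, as in [cea_model()].
#' @return The annual price in US$, or `NA` with a `reason` attribute when
#'   the QALY delta is not positive (no finite price attains the
#'   threshold).
#' @export
#' @examples
#' p <- ad_parameters()
#' value_based_price(p, "lecanemab", "soc", 150000)
value_based_price <- function(params, strategy, reference, wtp,
                              hr_method = c("multiplicative", "rate_based"),
                              half_cycle = FALSE) {
  hr_method <- match.arg(hr_method)
  s <- params$strategies[[strategy]]
  r <- params$strategies[[reference]]
  if (is.null(s) || is.null(r)) stop("unknown strategy name", call. = FALSE)
  if (!strategy_has_drug(s)) stop("strategy '", strategy, "' has no drug price", call. = FALSE)

  tr_s <- simulate_cohort(params, s, hr_method = hr_method)
  tr_r <- simulate_cohort(params, r, hr_method = hr_method)
  e_s <- accumulate_outcomes(tr_s, params, s, half_cycle)
  e_r <- accumulate_outcomes(tr_r, params, r, half_cycle)
  dq <- e_s$qaly - e_r$qaly
  if (dq <= 0) {
    return(structure(NA_real_, reason = "QALY delta is not positive; no finite price attains the threshold"))
  }
  # cost(p) = cost0 - D0 + p * Y, with D0 the current discounted drug outlay
  # and Y the discounted treated-years
  n <- nrow(tr_s$occupancy)
  rate <- s$discount_rate %||% params$discount_rate
  df <- discount_factor(rate, seq_len(n) - 1)
  w <- rep(1, n)
  if (half_cycle && n > 1) { w[1] <- 0.5; w[n] <- 0.5 }
  prices <- drug_price_at(s$drug_price_schedule, seq_len(n) - 1L)
  D0 <- sum(prices * tr_s$on_treatment * w * df)
  Y <- sum(tr_s$on_treatment * w * df)
  (wtp * dq + e_r$cost - (e_s$cost - D0)) / Y
}
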