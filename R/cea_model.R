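# Central evaluator: simulate every strategy, accumulate outcomes, and run
# the pairwise incremental analysis.

default_comparisons <- function(params) {
  ref <- reference_strategy_name(params)
  trt <- treated_strategy_names(params)
  pairs <- lapply(trt, function(nm) c(nm, ref))
  if (length(trt) >= 2) {
    for (i in seq_len(length(trt) - 1)) {
      pairs <- c(pairs, lapply(seq(i + 1, length(trt)), function(j) c(trt[j], trt[i])))
    }
  }
  pairs
}

#' Evaluate the cost-effectiveness model
#'
#' Runs the full base case for a configuration: simulates every strategy's
#' cohort to the age cap, accumulates discounted life-years, QALYs and
#' costs, and performs the pairwise incremental analysis with ICERs and
#' dominance classification. The default comparisons are every treated
#' strategy versus the reference arm, plus treated strategies against each
#' other in list order (for the shipped configuration: aducanumab vs SoC,
#' lecanemab vs SoC, lecanemab vs aducanumab).
#'
#' @param params An `ad_parameters` object (validated before use).
#' @param comparisons Optional list of `c(intervention, reference)` pairs.
#' @param hr_method Hazard-ratio conversion; the shipped default is
#'   `"multiplicative"` (see [apply_hazard_ratio()] and the methods
#'   vignette).
#' @param half_cycle Apply a half-cycle correction? Off in the base case.
#' @param wtp Willingness-to-pay threshold for the cost-effectiveness flag.
#' @param age_cap,stop_tol Optional overrides of the simulation horizon.
#' @param validate Validate `params` first (on by default; the PSA skips
#'   re-validation of its own structurally guaranteed draws).
#' @return An object of class `"cea_model"` with components `results`
#'   (named list of [accumulate_outcomes()] results), `traces`,
#'   `comparisons` (a `cea_comparison` data frame), `config`, `params`.
#' @export
#' @examples
#' fit <- cea_model(ad_parameters())
#' fit
#' summary(fit)
cea_model <- function(params,
                      comparisons = NULL,
                      hr_method = c("multiplicative", "rate_based"),
                      half_cycle = FALSE,
                      wtp = NULL,
                      age_cap = NULL,
                      stop_tol = NULL,
                      validate = TRUE) {
  hr_method <- match.arg(hr_method)
  if (validate) {
    v <- validate_parameters(params)
    if (length(v)) {
      stop("invalid model configuration:\n  - ", paste(v, collapse = "\n  - "),
           call. = FALSE)
    }
  }
  wtp <- wtp %||% params$wtp_default
  comparisons <- comparisons %||% default_comparisons(params)

  traces <- lapply(params$strategies, function(s) {
    simulate_cohort(params, s, hr_method = hr_method,
                    age_cap = age_cap, stop_tol = stop_tol)
  })
  results <- lapply(names(params$strategies), function(nm) {
    accumulate_outcomes(traces[[nm]], params, params$strategies[[nm]], half_cycle)
  })
  names(results) <- names(params$strategies)

  structure(list(
    results = results,
    traces = traces,
    comparisons = incremental_analysis(results, comparisons, wtp),
    config = list(hr_method = hr_method, half_cycle = half_cycle,
                  wtp = wtp, age_cap = age_cap %||% params$age_cap,
                  stop_tol = stop_tol %||% params$stop_tol,
                  discount_rate = params$discount_rate),
    params = params
  ), class = "cea_model")
}

format_icer <- function(icer, dominance) {
  ifelse(dominance != "", dominance, formatC(icer, format = "f", digits = 2, big.mark = ","))
}

#' @export
print.cea_model <- function(x, ...) {
  cat("Markov cohort cost-effectiveness model\n")
  cat(sprintf("  hr_method=%s  half_cycle=%s  age_cap=%s  WTP=%s US$/QALY\n",
              x$config$hr_method, x$config$half_cycle, x$config$age_cap,
              format(x$config$wtp, big.mark = ",")))
  cmp <- x$comparisons
  cat("\nIncremental analysis (discounted):\n")
  disp <- data.frame(
    comparison = paste(cmp$intervention, "vs", cmp$reference),
    delta_cost = round(cmp$delta_cost, 2),
    delta_ly = round(cmp$delta_ly, 2),
    delta_qaly = round(cmp$delta_qaly, 2),
    icer_per_ly = format_icer(cmp$icer_per_ly, cmp$dominance),
    icer_per_qaly = format_icer(cmp$icer_per_qaly, cmp$dominance),
    cost_effective = cmp$cost_effective
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  res <- object$results
  abs_tab <- data.frame(
    strategy = names(res),
    cost = vapply(res, `[[`, numeric(1), "cost"),
    ly = vapply(res, `[[`, numeric(1), "ly"),
    qaly = vapply(res, `[[`, numeric(1), "qaly"),
    cost_undisc = vapply(res, `[[`, numeric(1), "cost_undisc"),
    ly_undisc = vapply(res, `[[`, numeric(1), "ly_undisc"),
    qaly_undisc = vapply(res, `[[`, numeric(1), "qaly_undisc"),
    row.names = NULL
  )
  out <- list(strategies = abs_tab, comparisons = object$comparisons,
              config = object$config)
  class(out) <- "summary.cea_model"
  out
}

#' @export
print.summary.cea_model <- function(x, ...) {
  cat("Per-strategy discounted outcomes:\n")
  tab <- x$strategies
  tab$cost <- round(tab$cost, 2)
  tab$ly <- round(tab$ly, 4)
  tab$qaly <- round(tab$qaly, 4)
  tab$cost_undisc <- round(tab$cost_undisc, 2)
  tab$ly_undisc <- round(tab$ly_undisc, 4)
  tab$qaly_undisc <- round(tab$qaly_undisc, 4)
  print(tab, row.names = FALSE)
  cat("\nIncremental analysis:\n")
  cmp <- x$comparisons
  disp <- data.frame(
    comparison = paste(cmp$intervention, "vs", cmp$reference),
    delta_cost = round(cmp$delta_cost, 2),
    delta_qaly = round(cmp$delta_qaly, 2),
    icer_per_qaly = format_icer(cmp$icer_per_qaly, cmp$dominance)
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cea_model <- function(x, states = alive_states(), ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  nstrat <- length(x$traces)
  graphics::par(mfrow = c(1, nstrat), mar = c(4, 4, 2, 1))
  for (nm in names(x$traces)) {
    tr <- x$traces[[nm]]
    graphics::matplot(tr$ages, tr$occupancy[, states, drop = FALSE],
                      type = "l", lty = 1, lwd = 2,
                      xlab = "age (years)", ylab = "occupancy",
                      main = nm, ylim = c(0, 1), ...)
    graphics::legend("topright", legend = states, col = seq_along(states),
                     lty = 1, lwd = 2, cex = 0.7, bty = "n")
  }
  invisible(x)
}
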