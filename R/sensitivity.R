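# One-way (tornado) and probabilistic sensitivity analyses.

eval_comparison <- function(params, comparison, hr_method, half_cycle, wtp) {
  fit <- cea_model(params, comparisons = list(comparison),
                   hr_method = hr_method, half_cycle = half_cycle, wtp = wtp)
  fit$comparisons[1, ]
}

#' One-way sensitivity analysis (tornado data)
#'
#' For every parameter with a configured OSA range, re-runs the full base
#' case twice — once with the parameter at its lower limit and once at its
#' upper limit, all other parameters at base values — and records the ICER
#' per QALY of the requested comparison at both ends. Entries are sorted by
#' spread (the absolute ICER difference), the usual tornado ordering. A
#' limit that produces an invalid configuration is skipped with a warning
#' naming the parameter.
#'
#' @param params An `ad_parameters` object.
#' @param comparison Character pair `c(intervention, reference)`.
#' @param hr_method,half_cycle Model configuration, as in [cea_model()].
#' @return Data frame of class `"cea_tornado"` with columns `parameter`,
#'   `low_input`, `high_input`, `icer_low`, `icer_high`, `spread`.
#' @export
#' @examples
#' \donttest{
#' tor <- one_way_sensitivity(ad_parameters(), c("lecanemab", "aducanumab"))
#' head(tor, 3)
#' }
one_way_sensitivity <- function(params,
                                comparison = c("lecanemab", "aducanumab"),
                                hr_method = c("multiplicative", "rate_based"),
                                half_cycle = FALSE) {
  hr_method <- match.arg(hr_method)
  base <- eval_comparison(params, comparison, hr_method, half_cycle, params$wtp_default)
  rows <- list()
  for (nm in names(params$osa_ranges)) {
    r <- params$osa_ranges[[nm]]
    icers <- numeric(2)
    bad <- FALSE
    for (k in 1:2) {
      pk <- set_param(params, nm, r[k])
      viol <- validate_parameters(pk)
      if (length(viol)) {
        warning("OSA limit for '", nm, "' violates a model invariant; skipped (",
                viol[1], ")", call. = FALSE)
        bad <- TRUE
        break
      }
      icers[k] <- eval_comparison(pk, comparison, hr_method, half_cycle,
                                  params$wtp_default)$icer_per_qaly
    }
    if (bad) next
    rows[[nm]] <- data.frame(parameter = nm,
                             low_input = r[1], high_input = r[2],
                             icer_low = icers[1], icer_high = icers[2],
                             spread = abs(icers[2] - icers[1]),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "comparison") <- comparison
  attr(out, "base_icer") <- base$icer_per_qaly
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' @export
plot.cea_tornado <- function(x, n = 12, ...) {
  x <- x[seq_len(min(n, nrow(x))), ]
  x <- x[rev(seq_len(nrow(x))), ]
  base <- attr(x, "base_icer")
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::par(mar = c(4, 14, 2, 1))
  lo <- pmin(x$icer_low, x$icer_high)
  hi <- pmax(x$icer_low, x$icer_high)
  graphics::plot(NA, xlim = range(c(lo, hi, base)), ylim = c(0.5, nrow(x) + 0.5),
                 yaxt = "n", xlab = "ICER (US$/QALY)", ylab = "", ...)
  graphics::axis(2, at = seq_len(nrow(x)), labels = x$parameter, las = 1, cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(x)) - 0.35, hi, seq_len(nrow(x)) + 0.35,
                 col = "steelblue", border = NA)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

# ---- distribution machinery ------------------------------------------------

# moment matching: the distribution MEAN equals m, SD equals s
match_beta <- function(m, s) {
  if (s^2 >= m * (1 - m)) {
    stop("beta moment matching infeasible: se^2 >= mean*(1-mean) for mean ",
         m, call. = FALSE)
  }
  k <- m * (1 - m) / s^2 - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

match_gamma <- function(m, s) {
  c(shape = (m / s)^2, scale = s^2 / m)
}

match_lognormal <- function(m, s) {
  sigma2 <- log(1 + s^2 / m^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

draw_value <- function(family, m, s, n = 1) {
  if (s == 0 || family == "fixed") return(rep(m, n))
  switch(family,
    beta = {
      p <- match_beta(m, s)
      stats::rbeta(n, p[["shape1"]], p[["shape2"]])
    },
    gamma = {
      p <- match_gamma(m, s)
      stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]])
    },
    lognormal = {
      p <- match_lognormal(m, s)
      stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
    },
    stop("unknown distribution family '", family, "'", call. = FALSE)
  )
}

#' Draw one PSA parameter set
#'
#' Draws every uncertain parameter from its configured family, moment
#' matched so that the distribution mean equals the base-case value and the
#' standard deviation equals the resolved SE (reported SE, or mean/10 when
#' unreported); parameters with family `"fixed"` are left untouched. Draws
#' are independent across parameters, except that a strategy-level
#' progression hazard ratio (`strategy.NAME.hr`) is drawn once and applied
#' to all of that strategy's transitions. After drawing, transition rows
#' are re-validated; a row whose off-diagonal sum exceeds 1 is redrawn
#' (the redraw count is returned as an attribute).
#'
#' @param params An `ad_parameters` object.
#' @param max_redraws Maximum redraw attempts per transition row.
#' @return A new `ad_parameters` object with attributes `draws` (named
#'   vector of the values drawn) and `redraws` (count).
#' @export
draw_parameters <- function(params, max_redraws = 100) {
  drawn <- params
  vals <- numeric(0)
  trans_names <- character(0)
  for (nm in names(params$psa_distributions)) {
    spec <- params$psa_distributions[[nm]]
    m <- get_param(params, nm)
    s <- resolve_psa_se(list(family = spec$family, mean = m, se = spec$se))
    if (spec$family == "fixed" || s == 0) next
    val <- tryCatch(draw_value(spec$family, m, s),
                    error = function(e) stop("PSA draw failed for '", nm, "': ",
                                             conditionMessage(e), call. = FALSE))
    drawn <- set_param(drawn, nm, val)
    vals[nm] <- val
    if (startsWith(nm, "transition.")) trans_names <- c(trans_names, nm)
  }

  redraws <- 0
  repeat {
    bad_rows <- alive_states()[vapply(alive_states(), function(s) {
      sum(drawn$soc_transitions[s, setdiff(alive_states(), s)]) > 1
    }, logical(1))]
    if (length(bad_rows) == 0) break
    redraws <- redraws + 1
    if (redraws > max_redraws) {
      stop("transition row(s) ", paste(bad_rows, collapse = ", "),
           " remain infeasible after ", max_redraws, " redraws", call. = FALSE)
    }
    for (s in bad_rows) {
      for (nm in trans_names[startsWith(trans_names, paste0("transition.", s, "."))]) {
        spec <- params$psa_distributions[[nm]]
        m <- get_param(params, nm)
        se <- resolve_psa_se(list(family = spec$family, mean = m, se = spec$se))
        val <- draw_value(spec$family, m, se)
        drawn <- set_param(drawn, nm, val)
        vals[nm] <- val
      }
    }
  }
  attr(drawn, "draws") <- vals
  attr(drawn, "redraws") <- redraws
  drawn
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_draws` Monte Carlo evaluations of the full model, one per drawn
#' parameter set (see [draw_parameters()]), recording the discounted cost,
#' life-year and QALY deltas of every comparison with all strategies
#' evaluated on the same draw. Fully reproducible from `seed`.
#'
#' @param params An `ad_parameters` object.
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed for the random source.
#' @param comparisons Optional list of `c(intervention, reference)` pairs.
#' @param hr_method,half_cycle Model configuration, as in [cea_model()].
#' @return Object of class `"cea_psa"`: `samples` (long data frame: draw,
#'   intervention, reference, delta_cost, delta_ly, delta_qaly), `draws`
#'   (data frame of drawn parameter values), `base` (base-case comparison
#'   table), `seed`, `n_draws`.
#' @export
run_psa <- function(params, n_draws = 1000, seed = NULL,
                    comparisons = NULL,
                    hr_method = c("multiplicative", "rate_based"),
                    half_cycle = FALSE) {
  hr_method <- match.arg(hr_method)
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  comparisons <- comparisons %||% default_comparisons(params)
  base_fit <- cea_model(params, comparisons = comparisons,
                        hr_method = hr_method, half_cycle = half_cycle)

  samples <- vector("list", n_draws)
  draw_rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    pk <- tryCatch(draw_parameters(params),
                   error = function(e) stop("PSA draw ", i, " failed: ",
                                            conditionMessage(e), call. = FALSE))
    fit <- cea_model(pk, comparisons = comparisons,
                     hr_method = hr_method, half_cycle = half_cycle,
                     validate = FALSE)
    cmp <- fit$comparisons
    samples[[i]] <- data.frame(draw = i,
                               intervention = cmp$intervention,
                               reference = cmp$reference,
                               delta_cost = cmp$delta_cost,
                               delta_ly = cmp$delta_ly,
                               delta_qaly = cmp$delta_qaly,
                               stringsAsFactors = FALSE)
    draw_rows[[i]] <- attr(pk, "draws")
  }
  draws <- do.call(rbind, draw_rows)
  structure(list(
    samples = do.call(rbind, samples),
    draws = as.data.frame(draws),
    base = base_fit$comparisons,
    seed = seed,
    n_draws = n_draws,
    config = list(hr_method = hr_method, half_cycle = half_cycle)
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_draws, "draws",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  cmps <- unique(x$samples[, c("intervention", "reference")])
  for (i in seq_len(nrow(cmps))) {
    s <- x$samples[x$samples$intervention == cmps$intervention[i] &
                     x$samples$reference == cmps$reference[i], ]
    cat(sprintf("  %s vs %s: mean dC=%.0f mean dQALY=%.4f P(dQALY>0)=%.3f\n",
                cmps$intervention[i], cmps$reference[i],
                mean(s$delta_cost), mean(s$delta_qaly), mean(s$delta_qaly > 0)))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each comparison and each willingness-to-pay value on the grid,
#' computes the fraction of PSA samples with positive net monetary benefit
#' `wtp * delta_qaly - delta_cost`.
#'
#' @param psa A `cea_psa` object (or its `samples` data frame).
#' @param wtp_grid Ascending grid of willingness-to-pay values, US$/QALY.
#' @return Data frame of class `"cea_ceac"` with columns `intervention`,
#'   `reference`, `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e6, by = 1e4)) {
  samples <- if (inherits(psa, "cea_psa")) psa$samples else psa
  stopifnot(nrow(samples) > 0, !is.unsorted(wtp_grid))
  cmps <- unique(samples[, c("intervention", "reference")])
  out <- list()
  for (i in seq_len(nrow(cmps))) {
    s <- samples[samples$intervention == cmps$intervention[i] &
                   samples$reference == cmps$reference[i], ]
    prob <- vapply(wtp_grid, function(l) mean(l * s$delta_qaly - s$delta_cost > 0),
                   numeric(1))
    out[[i]] <- data.frame(intervention = cmps$intervention[i],
                           reference = cmps$reference[i],
                           wtp = wtp_grid, probability = prob,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' @export
plot.cea_ceac <- function(x, ...) {
  cmps <- unique(x[, c("intervention", "reference")])
  graphics::plot(NA, xlim = range(x$wtp), ylim = c(0, 1),
                 xlab = "willingness to pay (US$/QALY)",
                 ylab = "probability cost-effective", ...)
  for (i in seq_len(nrow(cmps))) {
    s <- x[x$intervention == cmps$intervention[i] & x$reference == cmps$reference[i], ]
    graphics::lines(s$wtp, s$probability, col = i, lwd = 2)
  }
  graphics::legend("bottomright",
                   legend = paste(cmps$intervention, "vs", cmps$reference),
                   col = seq_len(nrow(cmps)), lwd = 2, bty = "n")
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Willingness-to-pay value where a CEAC reaches a probability level
#'
#' Returns the smallest grid value at which the curve's probability reaches
#' `level`, linearly interpolated between the bracketing grid points. When
#' the level is never reached, returns `NA` with the maximum attained
#' probability as an attribute.
#'
#' @param curve A `cea_ceac` data frame (one comparison, or filtered via
#'   `intervention`/`reference`).
#' @param level Probability level sought (default 0.5).
#' @param intervention,reference Optional filters when `curve` holds
#'   several comparisons.
#' @return WTP in US$/QALY, or labelled `NA`.
#' @export
ceac_crossing <- function(curve, level = 0.5,
                          intervention = NULL, reference = NULL) {
  if (!is.null(intervention)) curve <- curve[curve$intervention == intervention, ]
  if (!is.null(reference)) curve <- curve[curve$reference == reference, ]
  stopifnot(nrow(curve) > 0)
  p <- curve$probability
  g <- curve$wtp
  i <- which(p >= level)[1]
  if (is.na(i)) {
    return(structure(NA_real_, max_probability = max(p)))
  }
  if (i == 1) return(g[1])
  # linear interpolation between the bracketing grid points
  g[i - 1] + (level - p[i - 1]) / (p[i] - p[i - 1]) * (g[i] - g[i - 1])
}
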