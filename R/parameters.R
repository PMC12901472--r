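# Model configuration: construction, file I/O, validation, and a dotted-path
# resolver used by the one-way and probabilistic sensitivity analyses.

#' Define a treatment strategy
#'
#' A strategy bundles everything that distinguishes one arm of the analysis:
#' the hazard ratios it applies to disease-progression transitions, its drug
#' price schedule, annual administration and ARIA-monitoring costs, the ARIA
#' event rate, the starting age and starting state distribution of its
#' cohort, and the rule deciding how long treatment costs accrue.
#'
#' @param name Strategy label.
#' @param hr_progression Named numeric vector of hazard ratios versus the
#'   reference strategy; names are transitions written `"FROM->TO"` (e.g.
#'   `"MCI->MILD"`). Transitions not listed keep a hazard ratio of 1.
#' @param drug_price_schedule Data frame with columns `from_cycle` and
#'   `price` (annual US$); the schedule must start at cycle 0. An empty data
#'   frame means no drug cost.
#' @param admin_annual Annual administration (infusion) cost, US$. Charged
#'   only to strategies with a non-zero drug price.
#' @param aria_rate Annual probability of an ARIA event (kept for audit and
#'   for deriving the ARIA cost via [aria_annual_cost()]).
#' @param aria_annual Annual ARIA monitoring cost, US$. For drug strategies
#'   it accrues on the treated fraction; for the reference strategy on the
#'   alive fraction.
#' @param start_age Cohort starting age in years (may be fractional).
#' @param start_distribution Named numeric vector over `MCI` and `MILD`
#'   summing to 1.
#' @param treatment_rule One of `"while_early_AD"` (drug, administration and
#'   ARIA costs accrue in proportion to MCI+MILD occupancy), `"lifetime"`
#'   (accrue while alive) or `"none"` (untreated reference).
#' @param discount_rate Optional per-strategy annual discount rate; `NULL`
#'   falls back to the global rate.
#' @return A list of class `"strategy_spec"`.
#' @export
strategy_spec <- function(name,
                          hr_progression = numeric(0),
                          drug_price_schedule = data.frame(from_cycle = integer(0),
                                                           price = numeric(0)),
                          admin_annual = 0,
                          aria_rate = 0,
                          aria_annual = 0,
                          start_age = 71.4,
                          start_distribution = c(MCI = 0.615, MILD = 0.385),
                          treatment_rule = c("while_early_AD", "lifetime", "none"),
                          discount_rate = NULL) {
  treatment_rule <- match.arg(treatment_rule)
  structure(list(
    name = name,
    hr_progression = hr_progression,
    drug_price_schedule = drug_price_schedule,
    admin_annual = admin_annual,
    aria_rate = aria_rate,
    aria_annual = aria_annual,
    start_age = start_age,
    start_distribution = start_distribution,
    treatment_rule = treatment_rule,
    discount_rate = discount_rate
  ), class = "strategy_spec")
}

#' Default model configuration (published base case)
#'
#' Builds the complete shipped configuration of the early-AD
#' cost-effectiveness model: standard-of-care annual transition
#' probabilities, age-band all-cause mortality with stage-specific mortality
#' hazard ratios, state utilities, shared outpatient/inpatient costs, the
#' three strategies (SoC, aducanumab, lecanemab), the 3% annual discount
#' rate, the $150,000/QALY willingness-to-pay default, and per-parameter
#' distribution and range metadata for the probabilistic and one-way
#' sensitivity analyses.
#'
#' Notes on derived entries: the aducanumab ARIA monitoring cost is not
#' published and is set equal to the lecanemab value; administration cost is
#' per infusion, so the aducanumab arm (one infusion every 4 weeks) accrues
#' half the annual administration cost of the biweekly lecanemab arm; all
#' three strategies share the lecanemab-trial starting distribution
#' (61.5% MCI / 38.5% mild) so that incremental results compare treatments
#' on a common cohort. The trial placebo split (66.2% MCI) can be restored
#' with `set_param(p, "strategy.soc.start_mci", 0.662)`.
#'
#' @return An object of class `"ad_parameters"`.
#' @seealso [load_parameters()], [validate_parameters()], [set_param()]
#' @export
#' @examples
#' p <- ad_parameters()
#' get_param(p, "transition.MCI.MILD")
ad_parameters <- function() {
  st <- health_states()
  tp <- matrix(0, 5, 5, dimnames = list(st, st))
  tp["MCI", "MILD"] <- 0.32
  tp["MCI", "MODERATE"] <- 0.04
  tp["MCI", "SEVERE"] <- 0.01
  tp["MILD", "MCI"] <- 0.03
  tp["MILD", "MODERATE"] <- 0.36
  tp["MILD", "SEVERE"] <- 0.05
  tp["MODERATE", "MILD"] <- 0.04
  tp["MODERATE", "SEVERE"] <- 0.40
  tp["SEVERE", "MODERATE"] <- 0.02

  # administration is a per-infusion fee: 26 biweekly infusions/yr for
  # lecanemab, 13 four-weekly infusions/yr for aducanumab
  admin_lec <- 3654.17
  admin_adu <- admin_lec / 2

  strategies <- list(
    soc = strategy_spec(
      name = "soc",
      treatment_rule = "none",
      start_age = 71.0,
      start_distribution = c(MCI = 0.615, MILD = 0.385),
      aria_rate = 0.06,
      aria_annual = 66.73
    ),
    aducanumab = strategy_spec(
      name = "aducanumab",
      hr_progression = c("MCI->MILD" = 0.83),
      drug_price_schedule = data.frame(from_cycle = c(0L, 1L),
                                       price = c(20500, 28200)),
      admin_annual = admin_adu,
      aria_rate = 0.15,        # assumed equal to lecanemab (not published)
      aria_annual = 154.82,    # assumed equal to lecanemab (not published)
      start_age = 71.4,
      start_distribution = c(MCI = 0.615, MILD = 0.385),
      treatment_rule = "while_early_AD"
    ),
    lecanemab = strategy_spec(
      name = "lecanemab",
      hr_progression = c("MCI->MILD" = 0.69, "MILD->MODERATE" = 0.69),
      drug_price_schedule = data.frame(from_cycle = 0L, price = 26500),
      admin_annual = admin_lec,
      aria_rate = 0.15,
      aria_annual = 154.82,
      start_age = 71.4,
      start_distribution = c(MCI = 0.615, MILD = 0.385),
      treatment_rule = "while_early_AD"
    )
  )

  psa <- list(
    "strategy.lecanemab.hr"             = list(family = "lognormal", se = NULL),
    "strategy.aducanumab.hr"            = list(family = "lognormal", se = NULL),
    "transition.MCI.MILD"               = list(family = "beta", se = NULL),
    "transition.MCI.MODERATE"           = list(family = "beta", se = NULL),
    "transition.MCI.SEVERE"             = list(family = "beta", se = NULL),
    "transition.MILD.MCI"               = list(family = "beta", se = NULL),
    "transition.MILD.MODERATE"          = list(family = "beta", se = NULL),
    "transition.MILD.SEVERE"            = list(family = "beta", se = NULL),
    "transition.MODERATE.MILD"          = list(family = "beta", se = NULL),
    "transition.MODERATE.SEVERE"        = list(family = "beta", se = NULL),
    "transition.SEVERE.MODERATE"        = list(family = "beta", se = NULL),
    "utility.MCI"                       = list(family = "beta", se = 0.02),
    "utility.MILD"                      = list(family = "beta", se = 0.01),
    "utility.MODERATE"                  = list(family = "beta", se = 0.01),
    "utility.SEVERE"                    = list(family = "beta", se = 0.01),
    "cost.outpatient"                   = list(family = "gamma", se = 251.30),
    "cost.inpatient"                    = list(family = "gamma", se = 1145.99),
    "strategy.lecanemab.admin_annual"   = list(family = "gamma", se = NULL),
    "strategy.aducanumab.admin_annual"  = list(family = "gamma", se = NULL),
    "strategy.lecanemab.aria_annual"    = list(family = "gamma", se = NULL),
    "strategy.aducanumab.aria_annual"   = list(family = "gamma", se = NULL),
    "strategy.soc.aria_annual"          = list(family = "gamma", se = NULL),
    "mortality.hr.MCI"                  = list(family = "lognormal", se = 0.16),
    "mortality.hr.MILD"                 = list(family = "lognormal", se = 0.19),
    "mortality.hr.MODERATE"             = list(family = "lognormal", se = 0.27),
    "mortality.hr.SEVERE"               = list(family = "lognormal", se = 0.37),
    "strategy.lecanemab.price"          = list(family = "fixed", se = NULL),
    "strategy.aducanumab.price"         = list(family = "fixed", se = NULL),
    "mortality.rate.65_74"              = list(family = "fixed", se = NULL),
    "mortality.rate.75_84"              = list(family = "fixed", se = NULL),
    "mortality.rate.85plus"             = list(family = "fixed", se = NULL)
  )

  osa <- list(
    "start_age.lecanemab_group"         = c(65, 75),
    "start_age.soc_group"               = c(65, 75),
    "strategy.lecanemab.hr.MCI.MILD"        = c(0.55, 0.83),
    "strategy.lecanemab.hr.MILD.MODERATE"   = c(0.55, 0.83),
    "strategy.aducanumab.hr.MCI.MILD"       = c(0.664, 0.996),  # derived +/-20%
    "transition.MCI.MILD"               = c(0.26, 0.38),
    "transition.MCI.MODERATE"           = c(0.03, 0.05),
    "transition.MCI.SEVERE"             = c(0.01, 0.01),
    "transition.MILD.MCI"               = c(0.02, 0.04),
    "transition.MILD.MODERATE"          = c(0.29, 0.43),
    "transition.MILD.SEVERE"            = c(0.04, 0.06),
    "transition.MODERATE.MILD"          = c(0.03, 0.05),
    "transition.MODERATE.SEVERE"        = c(0.32, 0.48),
    "transition.SEVERE.MODERATE"        = c(0.02, 0.02),
    "strategy.lecanemab.aria_rate"      = c(0.12, 0.18),
    "strategy.soc.aria_rate"            = c(0.05, 0.07),
    "strategy.lecanemab.price"          = c(21200, 31800),
    "strategy.aducanumab.price"         = c(16400, 24600),      # derived +/-20%
    "strategy.lecanemab.admin_annual"   = c(2923.34, 4385.01),
    "strategy.aducanumab.admin_annual"  = c(1461.67, 2192.50),  # derived +/-20%
    "cost.outpatient"                   = c(2589.81, 3884.72),
    "cost.inpatient"                    = c(14348.67, 21523.01),
    "strategy.lecanemab.aria_annual"    = c(123.86, 185.78),
    "strategy.aducanumab.aria_annual"   = c(123.86, 185.78),    # derived
    "strategy.soc.aria_annual"          = c(53.39, 80.08),
    "utility.MCI"                       = c(0.58, 0.88),
    "utility.MILD"                      = c(0.55, 0.83),
    "utility.MODERATE"                  = c(0.42, 0.64),
    "utility.SEVERE"                    = c(0.30, 0.46),
    "mortality.rate.65_74"              = c(0.02, 0.03),
    "mortality.rate.75_84"              = c(0.04, 0.06),
    "mortality.rate.85plus"             = c(0.13, 0.19),
    "mortality.hr.MCI"                  = c(1.46, 2.18),
    "mortality.hr.MILD"                 = c(2.34, 3.50),
    "mortality.hr.MODERATE"             = c(3.08, 4.62),
    "mortality.hr.SEVERE"               = c(7.62, 11.42),
    "discount.lecanemab_group"          = c(0.00, 0.08),
    "discount.soc_group"                = c(0.00, 0.08)
  )

  structure(list(
    soc_transitions = tp,
    mortality = list(
      age_bands = data.frame(min_age = c(65, 75, 85),
                             max_age = c(74, 84, Inf),
                             rate = c(0.02, 0.05, 0.16)),
      stage_hr = c(MCI = 1.82, MILD = 2.92, MODERATE = 3.85, SEVERE = 9.52)
    ),
    utilities = c(MCI = 0.73, MILD = 0.69, MODERATE = 0.53, SEVERE = 0.38),
    costs = list(outpatient = 3237.26, inpatient = 17935.84),
    strategies = strategies,
    discount_rate = 0.03,
    wtp_default = 150000,
    age_cap = 100,
    stop_tol = 1e-6,
    psa_distributions = psa,
    osa_ranges = osa
  ), class = "ad_parameters")
}

#' @export
print.ad_parameters <- function(x, ...) {
  cat("Early-AD Markov cohort model configuration\n")
  cat("  strategies     :", paste(names(x$strategies), collapse = ", "), "\n")
  cat("  discount rate  :", x$discount_rate, "\n")
  cat("  WTP default    :", format(x$wtp_default, big.mark = ","), "US$/QALY\n")
  cat("  age cap        :", x$age_cap, "\n")
  cat("  PSA parameters :", length(x$psa_distributions),
      " | OSA ranges:", length(x$osa_ranges), "\n")
  v <- validate_parameters(x)
  if (length(v)) cat("  ** INVALID:", length(v), "violation(s); see validate_parameters()\n")
  invisible(x)
}

band_labels <- c("65_74", "75_84", "85plus")

strategy_has_drug <- function(strategy) {
  nrow(strategy$drug_price_schedule) > 0 && any(strategy$drug_price_schedule$price > 0)
}

reference_strategy_name <- function(params) {
  nm <- names(params$strategies)
  is_ref <- vapply(params$strategies, function(s) {
    !strategy_has_drug(s) && (length(s$hr_progression) == 0 || all(s$hr_progression == 1))
  }, logical(1))
  nm[is_ref]
}

treated_strategy_names <- function(params) {
  setdiff(names(params$strategies), reference_strategy_name(params))
}

#' Read or modify a model parameter by dotted path
#'
#' Every quantity that the sensitivity analyses can vary is addressable by a
#' dotted name. Supported paths:
#' \describe{
#'   \item{`transition.FROM.TO`}{reference annual transition probability.}
#'   \item{`utility.STATE`}{state utility weight.}
#'   \item{`cost.outpatient`, `cost.inpatient`}{shared annual costs.}
#'   \item{`mortality.rate.65_74` / `.75_84` / `.85plus`}{age-band mortality.}
#'   \item{`mortality.hr.STATE`}{stage mortality hazard ratio.}
#'   \item{`strategy.NAME.hr`}{all progression hazard ratios of a strategy
#'     (one value applied to every listed transition; reading returns the
#'     first).}
#'   \item{`strategy.NAME.hr.FROM.TO`}{a single progression hazard ratio.}
#'   \item{`strategy.NAME.price`}{the first-year annual drug price; setting
#'     rescales the whole price schedule proportionally.}
#'   \item{`strategy.NAME.admin_annual` / `.aria_annual` / `.aria_rate` /
#'     `.start_age` / `.discount_rate` / `.start_mci`}{strategy fields
#'     (`start_mci` sets the MCI share, MILD taking the complement).}
#'   \item{`start_age.lecanemab_group` / `start_age.soc_group`}{starting age
#'     of all drug arms jointly (the aducanumab cohort is assumed identical
#'     to the lecanemab cohort) / of the reference arm.}
#'   \item{`discount.lecanemab_group` / `discount.soc_group`}{discount rate
#'     of all drug arms jointly / of the reference arm.}
#' }
#'
#' @param params An `ad_parameters` object.
#' @param name Dotted parameter path.
#' @param value Replacement value (for `set_param`).
#' @return `get_param` returns the numeric value; `set_param` the modified
#'   `ad_parameters` object.
#' @export
get_param <- function(params, name) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  root <- p[1]
  if (root == "transition" && length(p) == 3) {
    check_state(p[2]); check_state(p[3])
    return(params$soc_transitions[p[2], p[3]])
  }
  if (root == "utility" && length(p) == 2) {
    check_state(p[2])
    return(params$utilities[[p[2]]])
  }
  if (root == "cost" && length(p) == 2 && p[2] %in% names(params$costs)) {
    return(params$costs[[p[2]]])
  }
  if (root == "mortality" && length(p) == 3 && p[2] == "rate") {
    i <- match(p[3], band_labels)
    if (is.na(i) || i > nrow(params$mortality$age_bands)) {
      stop("unknown mortality band '", p[3], "'", call. = FALSE)
    }
    return(params$mortality$age_bands$rate[i])
  }
  if (root == "mortality" && length(p) == 3 && p[2] == "hr") {
    check_state(p[2:3][2])
    return(params$mortality$stage_hr[[p[3]]])
  }
  if (root == "start_age" && length(p) == 2) {
    nms <- group_strategies(params, p[2])
    return(params$strategies[[nms[1]]]$start_age)
  }
  if (root == "discount" && length(p) == 2) {
    nms <- group_strategies(params, p[2])
    s <- params$strategies[[nms[1]]]
    return(s$discount_rate %||% params$discount_rate)
  }
  if (root == "strategy" && length(p) >= 3) {
    s <- params$strategies[[p[2]]]
    if (is.null(s)) stop("unknown strategy '", p[2], "'", call. = FALSE)
    field <- p[3]
    if (field == "hr") {
      if (length(p) == 3) {
        if (length(s$hr_progression) == 0) return(1)
        return(unname(s$hr_progression[1]))
      }
      key <- paste0(p[4], "->", p[5])
      return(unname(s$hr_progression[key] %na% 1))
    }
    if (field == "price") {
      if (!strategy_has_drug(s)) return(0)
      return(s$drug_price_schedule$price[1])
    }
    if (field == "discount_rate") return(s$discount_rate %||% params$discount_rate)
    if (field == "start_mci") return(unname(s$start_distribution[["MCI"]]))
    if (field %in% c("admin_annual", "aria_annual", "aria_rate", "start_age")) {
      return(s[[field]])
    }
  }
  stop("unresolvable parameter name '", name, "'", call. = FALSE)
}

`%na%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

check_state <- function(s) {
  if (!s %in% health_states()) stop("unknown state '", s, "'", call. = FALSE)
}

group_strategies <- function(params, group) {
  if (group == "soc_group") return(reference_strategy_name(params))
  if (group == "lecanemab_group") return(treated_strategy_names(params))
  stop("unknown strategy group '", group, "'", call. = FALSE)
}

#' @rdname get_param
#' @export
set_param <- function(params, name, value) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  root <- p[1]
  if (root == "transition" && length(p) == 3) {
    check_state(p[2]); check_state(p[3])
    params$soc_transitions[p[2], p[3]] <- value
    return(params)
  }
  if (root == "utility" && length(p) == 2) {
    check_state(p[2])
    params$utilities[[p[2]]] <- value
    return(params)
  }
  if (root == "cost" && length(p) == 2 && p[2] %in% names(params$costs)) {
    params$costs[[p[2]]] <- value
    return(params)
  }
  if (root == "mortality" && length(p) == 3 && p[2] == "rate") {
    i <- match(p[3], band_labels)
    if (is.na(i)) stop("unknown mortality band '", p[3], "'", call. = FALSE)
    params$mortality$age_bands$rate[i] <- value
    return(params)
  }
  if (root == "mortality" && length(p) == 3 && p[2] == "hr") {
    params$mortality$stage_hr[[p[3]]] <- value
    return(params)
  }
  if (root == "start_age" && length(p) == 2) {
    for (nm in group_strategies(params, p[2])) {
      params$strategies[[nm]]$start_age <- value
    }
    return(params)
  }
  if (root == "discount" && length(p) == 2) {
    for (nm in group_strategies(params, p[2])) {
      params$strategies[[nm]]$discount_rate <- value
    }
    return(params)
  }
  if (root == "strategy" && length(p) >= 3) {
    nm <- p[2]
    if (is.null(params$strategies[[nm]])) {
      stop("unknown strategy '", nm, "'", call. = FALSE)
    }
    s <- params$strategies[[nm]]
    field <- p[3]
    if (field == "hr") {
      if (length(p) == 3) {
        s$hr_progression[] <- value
      } else {
        key <- paste0(p[4], "->", p[5])
        s$hr_progression[key] <- value
      }
    } else if (field == "price") {
      if (!strategy_has_drug(s)) stop("strategy '", nm, "' has no drug price", call. = FALSE)
      s$drug_price_schedule$price <-
        s$drug_price_schedule$price * (value / s$drug_price_schedule$price[1])
    } else if (field == "discount_rate") {
      s$discount_rate <- value
    } else if (field == "start_mci") {
      s$start_distribution <- c(MCI = value, MILD = 1 - value)
    } else if (field %in% c("admin_annual", "aria_annual", "aria_rate", "start_age")) {
      s[[field]] <- value
    } else {
      stop("unresolvable parameter name '", name, "'", call. = FALSE)
    }
    params$strategies[[nm]] <- s
    return(params)
  }
  stop("unresolvable parameter name '", name, "'", call. = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration and returns the
#' violations as a character vector (empty when the configuration is valid).
#' Nothing is raised: callers that require validity should
#' `stop()` on a non-empty result.
#'
#' @param params An `ad_parameters` object.
#' @return Character vector of violation descriptions, each naming the
#'   offending field and the violated rule.
#' @export
#' @examples
#' validate_parameters(ad_parameters())
validate_parameters <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  st <- health_states()
  al <- alive_states()

  tp <- params$soc_transitions
  if (!identical(dim(tp), c(5L, 5L))) {
    add("soc_transitions: must be a 5x5 matrix over the five health states")
    return(v)
  }
  if (any(tp < 0 | tp > 1)) add("soc_transitions: probabilities must lie in [0,1]")
  if (any(diag(tp) != 0)) add("soc_transitions: self-transitions must not be stored (diagonal must be 0)")
  if (any(tp["DEATH", ] != 0)) add("soc_transitions: DEATH row must be empty (absorbing state)")
  for (s in al) {
    rs <- sum(tp[s, setdiff(al, s)])
    if (rs > 1) add(sprintf("soc_transitions[%s,]: outgoing probabilities sum to %.3f > 1", s, rs))
  }

  ab <- params$mortality$age_bands
  if (nrow(ab) < 1 || ab$min_age[1] > 65 || !is.infinite(ab$max_age[nrow(ab)])) {
    add("mortality.age_bands: bands must cover [65, Inf)")
  }
  if (nrow(ab) > 1 && any(ab$min_age[-1] != ab$max_age[-nrow(ab)] + 1)) {
    add("mortality.age_bands: bands must be contiguous and non-overlapping")
  }
  if (any(ab$rate <= 0 | ab$rate >= 1)) add("mortality.age_bands.rate: rates must lie in (0,1)")
  shr <- params$mortality$stage_hr
  if (!all(al %in% names(shr))) add("mortality.stage_hr: must name every alive state")
  if (any(shr <= 0)) add("mortality.stage_hr: hazard ratios must be > 0")

  u <- params$utilities
  if (!all(al %in% names(u))) add("utilities: must name every alive state")
  if (any(u < 0 | u > 1)) add("utilities: weights must lie in [0,1]")

  if (params$costs$outpatient < 0) add("cost.outpatient: must be >= 0")
  if (params$costs$inpatient < 0) add("cost.inpatient: must be >= 0")

  for (nm in names(params$strategies)) {
    s <- params$strategies[[nm]]
    sd <- s$start_distribution
    if (!isTRUE(all.equal(sum(sd), 1)) || any(sd < 0) ||
        !all(names(sd) %in% early_ad_states())) {
      add(sprintf("strategy.%s.start_distribution: must be a non-negative split of MCI/MILD summing to 1", nm))
    }
    if (length(s$hr_progression) && any(s$hr_progression <= 0)) {
      add(sprintf("strategy.%s.hr_progression: hazard ratios must be > 0", nm))
    }
    sched <- s$drug_price_schedule
    if (nrow(sched)) {
      if (sched$from_cycle[1] != 0) add(sprintf("strategy.%s.drug_price_schedule: must start at cycle 0", nm))
      if (nrow(sched) > 1 && any(diff(sched$from_cycle) <= 0)) {
        add(sprintf("strategy.%s.drug_price_schedule: from_cycle must be strictly increasing", nm))
      }
      if (any(sched$price < 0)) add(sprintf("strategy.%s.drug_price_schedule: prices must be >= 0", nm))
    }
    for (f in c("admin_annual", "aria_annual")) {
      if (s[[f]] < 0) add(sprintf("strategy.%s.%s: must be >= 0", nm, f))
    }
    if (s$aria_rate < 0 || s$aria_rate > 1) add(sprintf("strategy.%s.aria_rate: must lie in [0,1]", nm))
    if (s$start_age < ab$min_age[1]) {
      add(sprintf("strategy.%s.start_age: below the first mortality band (%s)", nm, ab$min_age[1]))
    }
  }

  refs <- reference_strategy_name(params)
  if (length(refs) != 1) {
    add(sprintf("strategies: exactly one reference arm (all HR = 1, zero drug cost) required, found %d", length(refs)))
  }

  if (params$discount_rate < 0 || params$discount_rate > 0.5) {
    add("discount_rate: must lie in [0, 0.5]")
  }

  for (nm in names(params$psa_distributions)) {
    spec <- params$psa_distributions[[nm]]
    m <- tryCatch(get_param(params, nm), error = function(e) NULL)
    if (is.null(m)) {
      add(sprintf("psa_distributions['%s']: does not resolve to a model field", nm))
      next
    }
    if (!spec$family %in% c("lognormal", "beta", "gamma", "fixed")) {
      add(sprintf("psa_distributions['%s']: unknown family '%s'", nm, spec$family))
    }
    if (spec$family == "beta" && (m <= 0 || m >= 1)) {
      add(sprintf("psa_distributions['%s']: beta requires mean in (0,1), got %g", nm, m))
    }
    if (spec$family %in% c("gamma", "lognormal") && m <= 0) {
      add(sprintf("psa_distributions['%s']: %s requires mean > 0, got %g", nm, spec$family, m))
    }
    if (spec$family == "fixed" && !is.null(spec$se) && spec$se != 0) {
      add(sprintf("psa_distributions['%s']: family 'fixed' carries no se", nm))
    }
  }

  for (nm in names(params$osa_ranges)) {
    r <- params$osa_ranges[[nm]]
    ok <- tryCatch({ get_param(params, nm); TRUE }, error = function(e) FALSE)
    if (!ok) add(sprintf("osa_ranges['%s']: does not resolve to a model field", nm))
    if (r[1] > r[2]) add(sprintf("osa_ranges['%s']: lower limit exceeds upper limit", nm))
  }

  v
}

#' Standard error used for a PSA distribution
#'
#' Returns the reported standard error when present; otherwise falls back to
#' one tenth of the mean (the rule used when a source does not report an
#' SE). Fixed parameters have zero spread.
#'
#' @param spec A list with elements `family`, `mean`, and optionally `se`.
#' @return Standard error in the units of the mean.
#' @export
#' @examples
#' resolve_psa_se(list(family = "beta", mean = 0.73, se = 0.02))   # 0.02
#' resolve_psa_se(list(family = "lognormal", mean = 0.69))         # 0.069
resolve_psa_se <- function(spec) {
  if (identical(spec$family, "fixed")) return(0)
  if (!is.null(spec$se) && !is.na(spec$se)) return(spec$se)
  spec$mean / 10
}

# ---- file I/O --------------------------------------------------------------

params_to_list <- function(params) {
  tp <- params$soc_transitions
  tl <- list()
  for (s in alive_states()) {
    rv <- tp[s, ]
    row <- as.list(rv[rv > 0])
    if (length(row)) tl[[s]] <- row
  }
  strat <- lapply(params$strategies, function(s) {
    list(
      name = s$name,
      treatment_rule = s$treatment_rule,
      start_age = s$start_age,
      start_distribution = as.list(s$start_distribution),
      hr_progression = as.list(s$hr_progression),
      drug_price_schedule = if (nrow(s$drug_price_schedule)) {
        lapply(seq_len(nrow(s$drug_price_schedule)), function(i) {
          list(from_cycle = s$drug_price_schedule$from_cycle[i],
               price = s$drug_price_schedule$price[i])
        })
      } else list(),
      admin_annual = s$admin_annual,
      aria_rate = s$aria_rate,
      aria_annual = s$aria_annual,
      discount_rate = s$discount_rate
    )
  })
  list(
    discount_rate = params$discount_rate,
    wtp_default = params$wtp_default,
    age_cap = params$age_cap,
    stop_tol = params$stop_tol,
    soc_transitions = tl,
    utilities = as.list(params$utilities),
    mortality = list(
      age_bands = lapply(seq_len(nrow(params$mortality$age_bands)), function(i) {
        b <- params$mortality$age_bands[i, ]
        list(min_age = b$min_age,
             max_age = if (is.infinite(b$max_age)) "open" else b$max_age,
             rate = b$rate)
      }),
      stage_hr = as.list(params$mortality$stage_hr)
    ),
    costs = params$costs,
    strategies = strat,
    psa_distributions = params$psa_distributions,
    osa_ranges = lapply(params$osa_ranges, function(r) list(low = r[1], high = r[2]))
  )
}

require_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop("parameter file is missing required key '", where, key, "'", call. = FALSE)
  }
  x[[key]]
}

params_from_list <- function(y) {
  st <- health_states()
  tp <- matrix(0, 5, 5, dimnames = list(st, st))
  tl <- require_key(y, "soc_transitions", "")
  for (s in names(tl)) for (d in names(tl[[s]])) tp[s, d] <- as.numeric(tl[[s]][[d]])

  ab_raw <- require_key(require_key(y, "mortality", ""), "age_bands", "mortality.")
  ab <- data.frame(
    min_age = vapply(ab_raw, function(b) as.numeric(b$min_age), numeric(1)),
    max_age = vapply(ab_raw, function(b) {
      if (identical(b$max_age, "open")) Inf else as.numeric(b$max_age)
    }, numeric(1)),
    rate = vapply(ab_raw, function(b) as.numeric(b$rate), numeric(1))
  )

  strat_raw <- require_key(y, "strategies", "")
  strategies <- lapply(strat_raw, function(s) {
    sched <- s$drug_price_schedule
    sched_df <- if (length(sched)) {
      data.frame(from_cycle = vapply(sched, function(r) as.integer(r$from_cycle), integer(1)),
                 price = vapply(sched, function(r) as.numeric(r$price), numeric(1)))
    } else data.frame(from_cycle = integer(0), price = numeric(0))
    strategy_spec(
      name = s$name,
      hr_progression = unlist(s$hr_progression) %||% numeric(0),
      drug_price_schedule = sched_df,
      admin_annual = as.numeric(require_key(s, "admin_annual", paste0("strategies.", s$name, "."))),
      aria_rate = as.numeric(s$aria_rate %||% 0),
      aria_annual = as.numeric(require_key(s, "aria_annual", paste0("strategies.", s$name, "."))),
      start_age = as.numeric(require_key(s, "start_age", paste0("strategies.", s$name, "."))),
      start_distribution = unlist(require_key(s, "start_distribution", paste0("strategies.", s$name, "."))),
      treatment_rule = s$treatment_rule,
      discount_rate = if (is.null(s$discount_rate)) NULL else as.numeric(s$discount_rate)
    )
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "name")

  structure(list(
    soc_transitions = tp,
    mortality = list(age_bands = ab,
                     stage_hr = unlist(require_key(y$mortality, "stage_hr", "mortality."))),
    utilities = unlist(require_key(y, "utilities", "")),
    costs = list(outpatient = as.numeric(require_key(y$costs, "outpatient", "costs.")),
                 inpatient = as.numeric(require_key(y$costs, "inpatient", "costs."))),
    strategies = strategies,
    discount_rate = as.numeric(require_key(y, "discount_rate", "")),
    wtp_default = as.numeric(y$wtp_default %||% 150000),
    age_cap = as.numeric(y$age_cap %||% 100),
    stop_tol = as.numeric(y$stop_tol %||% 1e-6),
    psa_distributions = y$psa_distributions %||% list(),
    osa_ranges = lapply(y$osa_ranges %||% list(), function(r) {
      c(as.numeric(r$low), as.numeric(r$high))
    })
  ), class = "ad_parameters")
}

#' Load / write a model configuration file
#'
#' The configuration is stored as one YAML file whose sections mirror the
#' blocks of the published model-input table (transitions, utilities,
#' mortality, costs, strategies, PSA distributions, OSA ranges); the shipped
#' default lives at `system.file("extdata", "table1_params.yaml", package =
#' "adcea")`. Loading validates the result and fails on any violation;
#' missing keys are reported by name.
#'
#' @param path Path to a YAML configuration file.
#' @param params An `ad_parameters` object to serialize.
#' @return `load_parameters` returns a validated `ad_parameters` object;
#'   `write_parameters` returns `path` invisibly.
#' @export
#' @examples
#' p <- load_parameters(system.file("extdata", "table1_params.yaml", package = "adcea"))
#' get_param(p, "utility.MCI")
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  params <- params_from_list(y)
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid parameter file '", path, "':\n  - ",
         paste(v, collapse = "\n  - "), call. = FALSE)
  }
  params
}

#' @rdname load_parameters
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path, precision = 12)
  invisible(path)
}

#' Audit table of all sensitivity-analysis parameters
#'
#' One row per parameter named in the PSA distribution map or the OSA range
#' map: its dotted name, current value, resolved standard error, OSA limits
#' and distribution family. Useful for diffing a configuration against the
#' published inputs.
#'
#' @param params An `ad_parameters` object.
#' @return A data frame with columns `name`, `value`, `se`, `low`, `high`,
#'   `family`.
#' @export
params_audit <- function(params) {
  nms <- union(names(params$psa_distributions), names(params$osa_ranges))
  rows <- lapply(nms, function(nm) {
    val <- get_param(params, nm)
    spec <- params$psa_distributions[[nm]]
    fam <- if (is.null(spec)) NA_character_ else spec$family
    se <- if (is.null(spec)) NA_real_ else resolve_psa_se(list(family = spec$family, mean = val, se = spec$se))
    r <- params$osa_ranges[[nm]]
    data.frame(name = nm, value = val, se = se,
               low = if (is.null(r)) NA_real_ else r[1],
               high = if (is.null(r)) NA_real_ else r[2],
               family = fam, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
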