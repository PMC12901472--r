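# Synthetic model instances: randomized but structurally valid
# configurations, plus degenerate analytic fixtures with closed-form
# solutions, so the whole pipeline is testable without the shipped
# configuration file.

#' Generate a random, structurally valid model instance
#'
#' Produces a complete configuration (reference arm plus one intervention
#' arm) with randomized transition rows (off-diagonal sums kept below 0.9),
#' strictly decreasing utilities across severity, a randomized three-band
#' mortality schedule with increasing rates, non-negative costs, and a
#' known ground-truth progression hazard ratio for the intervention. Every
#' generated instance passes [validate_parameters()]; generation is
#' reproducible from `seed`.
#'
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param progression_intensity Scale of the off-diagonal transition mass
#'   per row, in (0, 0.9].
#' @param effect_hr Ground-truth hazard ratio of the synthetic intervention
#'   on its treated transitions.
#' @param drug_price Flat annual drug price of the intervention, US$.
#' @param n_treated_transitions How many progression transitions the
#'   intervention affects (1 or 2).
#' @return An `ad_parameters` object with attribute `true_hr`.
#' @export
#' @examples
#' inst <- generate_instance(seed = 1)
#' validate_parameters(inst)  # character(0)
generate_instance <- function(seed = NULL,
                              progression_intensity = 0.4,
                              effect_hr = 0.7,
                              drug_price = 10000,
                              n_treated_transitions = 2) {
  if (progression_intensity <= 0 || progression_intensity > 0.9) {
    stop("progression_intensity must lie in (0, 0.9]: row sums would be infeasible",
         call. = FALSE)
  }
  stopifnot(effect_hr > 0, drug_price >= 0,
            n_treated_transitions %in% c(1, 2))
  if (!is.null(seed)) set.seed(seed)

  params <- ad_parameters()
  st <- health_states()
  al <- alive_states()

  # transition rows: random off-diagonal mass, total < 0.9 per row
  tp <- matrix(0, 5, 5, dimnames = list(st, st))
  for (s in al) {
    dests <- setdiff(al, s)
    w <- stats::runif(length(dests))
    total <- progression_intensity * stats::runif(1, 0.3, 1)
    tp[s, dests] <- total * w / sum(w)
  }
  params$soc_transitions <- tp

  # strictly decreasing utilities across severity
  u <- sort(stats::runif(4, 0.2, 0.95), decreasing = TRUE)
  while (any(diff(u) >= -1e-3)) u <- sort(stats::runif(4, 0.2, 0.95), decreasing = TRUE)
  params$utilities <- setNames(u, al)

  # three-band mortality with increasing rates; stage HRs increasing-ish
  r <- sort(stats::runif(3, 0.01, 0.3))
  params$mortality$age_bands$rate <- r
  params$mortality$stage_hr <- setNames(sort(stats::runif(4, 0.8, 10)), al)

  params$costs$outpatient <- stats::runif(1, 500, 5000)
  params$costs$inpatient <- stats::runif(1, 2000, 25000)

  start_mci <- stats::runif(1, 0.3, 0.9)
  start_age <- stats::runif(1, 66, 80)
  treated <- c("MCI->MILD", "MILD->MODERATE")[seq_len(n_treated_transitions)]

  params$strategies <- list(
    soc = strategy_spec(
      name = "soc", treatment_rule = "none",
      start_age = start_age,
      start_distribution = c(MCI = start_mci, MILD = 1 - start_mci),
      aria_rate = stats::runif(1, 0, 0.2),
      aria_annual = stats::runif(1, 0, 200)
    ),
    intervention = strategy_spec(
      name = "intervention",
      hr_progression = setNames(rep(effect_hr, length(treated)), treated),
      drug_price_schedule = data.frame(from_cycle = 0L, price = drug_price),
      admin_annual = stats::runif(1, 0, 4000),
      aria_rate = stats::runif(1, 0, 0.3),
      aria_annual = stats::runif(1, 0, 300),
      start_age = start_age,
      start_distribution = c(MCI = start_mci, MILD = 1 - start_mci),
      treatment_rule = "while_early_AD"
    )
  )

  # keep sensitivity metadata consistent with the randomized fields
  params$psa_distributions <- list(
    "strategy.intervention.hr" = list(family = "lognormal", se = NULL),
    "utility.MCI" = list(family = "beta", se = NULL),
    "utility.MILD" = list(family = "beta", se = NULL),
    "cost.outpatient" = list(family = "gamma", se = NULL),
    "cost.inpatient" = list(family = "gamma", se = NULL)
  )
  params$osa_ranges <- list(
    "utility.MILD" = sort(c(0.9 * u[2], min(1, 1.1 * u[2]))),
    "cost.inpatient" = c(0.8, 1.2) * params$costs$inpatient,
    "strategy.intervention.price" = c(0.8, 1.2) * drug_price
  )

  attr(params, "true_hr") <- effect_hr
  params
}

#' Degenerate one-alive-state fixture with a closed-form solution
#'
#' Builds a configuration in which every alive-to-alive transition
#' probability is zero, mortality is a constant `p_death` at every age and
#' stage, and the cohort starts fully in MCI. Occupancy then follows the
#' geometric decay `(1 - p_death)^t`, and the discounted life-years over
#' `cycles` cycles have the closed form
#' `sum_t ((1 - p_death) / (1 + discount))^t`, returned alongside the
#' configuration as an independent oracle for the cohort engine.
#'
#' @param p_death Constant annual death probability, in (0, 1).
#' @param discount Annual discount rate.
#' @param cycles Number of cycles accumulated.
#' @return List with `params` (an `ad_parameters` object), `strategy` (the
#'   arm to simulate), `cycles`, and `expected_ly` (closed form).
#' @export
#' @examples
#' fx <- analytic_two_state_fixture(0.5, 0, 3)
#' fx$expected_ly  # 1.75
analytic_two_state_fixture <- function(p_death, discount = 0, cycles = 10) {
  stopifnot(p_death > 0, p_death < 1, discount >= 0, cycles >= 1)
  params <- ad_parameters()
  params$soc_transitions[] <- 0
  params$mortality$age_bands <- data.frame(min_age = 65, max_age = Inf, rate = p_death)
  params$mortality$stage_hr <- setNames(rep(1, 4), alive_states())
  params$utilities <- setNames(rep(1, 4), alive_states())
  params$discount_rate <- discount
  params$age_cap <- 65 + cycles - 1  # exactly `cycles` recorded cycles from age 65
  params$stop_tol <- 0
  params$strategies <- list(
    soc = strategy_spec(name = "soc", treatment_rule = "none",
                        start_age = 65,
                        start_distribution = c(MCI = 1, MILD = 0),
                        aria_annual = 0)
  )
  params$psa_distributions <- list()
  params$osa_ranges <- list()
  ratio <- (1 - p_death) / (1 + discount)
  list(params = params,
       strategy = "soc",
       cycles = cycles,
       expected_ly = sum(ratio^(seq_len(cycles) - 1)))
}

#' Recover a progression hazard ratio from noiseless cohort traces
#'
#' Given the reference configuration and the first two occupancy rows of an
#' intervention trace, inverts the engine's hazard-ratio transform: the
#' one-cycle occupancy is a monotone function of the (single, shared)
#' progression hazard ratio, so the root of
#' `occupancy_after_one_cycle(hr) = observed` recovers the truth exactly on
#' noiseless cohort fractions. Inverting with a different `hr_method` than
#' the one that generated the trace yields a visibly different estimate,
#' which callers can use as a transform-mismatch diagnostic.
#'
#' @param params The ground-truth `ad_parameters` (with the intervention's
#'   `hr_progression` entries marking which transitions are treated).
#' @param trace A `cea_trace` of the intervention arm (>= 2 cycles).
#' @param strategy Name of the intervention strategy.
#' @param target_state State whose cycle-1 occupancy is matched (default
#'   `"MILD"`, the destination of the canonical treated transition).
#' @param hr_method Transform assumed during inversion.
#' @return Estimated hazard ratio, or `NA` with a `reason` attribute when
#'   the source states have zero starting occupancy.
#' @export
recover_hr <- function(params, trace, strategy = "intervention",
                       target_state = "MILD",
                       hr_method = c("multiplicative", "rate_based")) {
  hr_method <- match.arg(hr_method)
  s <- params$strategies[[strategy]]
  if (is.null(s)) stop("unknown strategy '", strategy, "'", call. = FALSE)
  if (nrow(trace$occupancy) < 2) stop("trace needs at least 2 cycles", call. = FALSE)
  sources <- sub("->.*", "", names(s$hr_progression))
  if (sum(trace$occupancy[1, sources]) <= 0) {
    return(structure(NA_real_, reason = "zero occupancy in the treated source state(s)"))
  }
  observed <- trace$occupancy[2, target_state]
  x0 <- trace$occupancy[1, ]
  f <- function(hr) {
    s_try <- s
    s_try$hr_progression[] <- hr
    M <- build_transition_matrix(params, s_try, s$start_age, hr_method)
    (x0 %*% M)[1, target_state] - observed
  }
  # large hazard ratios can push a transition row past 1; step the upper
  # bracket down until the matrix is feasible
  upper <- 20
  repeat {
    val <- tryCatch(f(upper), error = function(e) NULL)
    if (!is.null(val)) break
    upper <- upper / 1.5
    if (upper < 1e-5) stop("no feasible hazard ratio bracket", call. = FALSE)
  }
  stats::uniroot(f, interval = c(1e-6, upper), tol = 1e-12)$root
}
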