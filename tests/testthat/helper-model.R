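# shared fixtures built in code

table1 <- ad_parameters()

# a null intervention: identical to the reference arm in everything that
# matters economically; used by exact-zero property tests
nullify_intervention <- function(params, strategy, reference = "soc") {
  s <- params$strategies[[strategy]]
  r <- params$strategies[[reference]]
  s$hr_progression[] <- 1
  s$drug_price_schedule <- data.frame(from_cycle = integer(0), price = numeric(0))
  s$admin_annual <- 0
  s$aria_annual <- r$aria_annual
  s$start_age <- r$start_age
  s$start_distribution <- r$start_distribution
  params$strategies[[strategy]] <- s
  params
}

# evaluate one comparison without requiring a unique reference arm
manual_comparison <- function(params, intervention, reference,
                              hr_method = "multiplicative", half_cycle = FALSE) {
  res <- lapply(params$strategies[c(intervention, reference)], function(s) {
    accumulate_outcomes(simulate_cohort(params, s, hr_method = hr_method),
                        params, s, half_cycle)
  })
  incremental_analysis(res, list(c(intervention, reference)),
                       wtp = params$wtp_default)
}

# all-fixed PSA metadata: every uncertain parameter degenerates to its mean
degenerate_psa <- function(params) {
  params$psa_distributions <- lapply(params$psa_distributions, function(spec) {
    list(family = "fixed", se = NULL)
  })
  params
}
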