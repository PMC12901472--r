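test_that("discounting and ARIA cost helpers match closed forms", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 0.970873786408, tolerance = 1e-9)
  expect_equal(discount_factor(0, 10), 1)
  expect_error(discount_factor(-0.01, 1))

  expect_equal(aria_annual_cost(344.04, 0.15), 154.82, tolerance = 1e-4)
  expect_equal(aria_annual_cost(1000, 0), 0)
  expect_equal(aria_annual_cost(100, 0.10), 30)
})

test_that("cycle costs assemble drug, administration, ARIA and care components", {
  p <- table1
  occ <- c(MCI = 1, MILD = 0, MODERATE = 0, SEVERE = 0, DEATH = 0)
  care <- 3237.26 + 17935.84

  lec <- p$strategies$lecanemab
  expect_equal(cycle_cost(p, lec, occ, 1, 0), 26500 + 3654.17 + 154.82 + care)

  adu <- p$strategies$aducanumab
  c0 <- cycle_cost(p, adu, occ, 1, 0)
  c1 <- cycle_cost(p, adu, occ, 1, 1)
  c9 <- cycle_cost(p, adu, occ, 1, 9)
  expect_equal(c1 - c0, 28200 - 20500)  # year-one vs maintenance price
  expect_equal(c9, c1)

  # reference arm: ARIA monitoring rides on the alive fraction, no drug/admin
  soc <- p$strategies$soc
  expect_equal(cycle_cost(p, soc, occ, 0, 0), care + 66.73)

  # no alive mass, no cost
  dead <- c(MCI = 0, MILD = 0, MODERATE = 0, SEVERE = 0, DEATH = 1)
  expect_equal(cycle_cost(p, soc, dead, 0, 3), 0)
  expect_equal(cycle_cost(p, lec, dead, 0, 3), 0)
})

test_that("accumulation reduces to single-cycle rewards and respects bounds", {
  p <- table1
  s <- p$strategies$soc
  tr <- simulate_cohort(p, s, max_cycles = 1)
  e <- accumulate_outcomes(tr, p, s)
  expect_equal(e$ly, 1)
  expect_equal(e$qaly, 0.615 * 0.73 + 0.385 * 0.69)

  pure_mci <- p
  pure_mci$strategies$soc$start_distribution <- c(MCI = 1, MILD = 0)
  tr1 <- simulate_cohort(pure_mci, pure_mci$strategies$soc, max_cycles = 1)
  expect_equal(accumulate_outcomes(tr1, pure_mci, pure_mci$strategies$soc)$qaly, 0.73)

  # unit utilities make QALYs equal LYs exactly
  pu <- p
  pu$utilities[] <- 1
  for (nm in names(pu$strategies)) {
    trn <- simulate_cohort(pu, pu$strategies[[nm]])
    en <- accumulate_outcomes(trn, pu, pu$strategies[[nm]])
    expect_equal(en$qaly, en$ly)
    expect_lte(en$qaly, en$ly + 1e-12)
    expect_lte(en$ly, en$ly_undisc)
    expect_lte(en$cost, en$cost_undisc)
  }
})

test_that("zero discount makes discounted and undiscounted outcomes identical", {
  p <- table1
  p$discount_rate <- 0
  for (nm in names(p$strategies)) p$strategies[[nm]]$discount_rate <- NULL
  fit <- cea_model(p)
  for (e in fit$results) {
    expect_identical(e$ly, e$ly_undisc)
    expect_identical(e$qaly, e$qaly_undisc)
    expect_identical(e$cost, e$cost_undisc)
  }
})

test_that("incremental analysis computes ICERs, dominance labels and WTP flags", {
  mk <- function(name, cost, qaly, ly = qaly) {
    structure(list(strategy = name, cost = cost, qaly = qaly, ly = ly),
              class = "econ_result")
  }
  res <- list(a = mk("a", 1100, 12), b = mk("b", 1000, 10),
              c = mk("c", 1200, 9.9), d = mk("d", 900, 11))
  cmp <- incremental_analysis(res, list(c("a", "b"), c("c", "b"), c("d", "b")),
                              wtp = 150)
  expect_equal(cmp$icer_per_qaly[1], 50)
  expect_equal(cmp$dominance, c("", "dominated", "dominant"))
  expect_true(cmp$cost_effective[1])
  expect_false(cmp$cost_effective[2])
  expect_true(cmp$cost_effective[3])

  tie <- incremental_analysis(list(a = mk("a", 1100, 10), b = mk("b", 1000, 10)),
                              list(c("a", "b")), wtp = 150)
  expect_equal(tie$dominance, "undefined")
  expect_true(is.na(tie$icer_per_qaly))
  expect_error(incremental_analysis(res, list(c("zz", "b"))), "zz")
})

test_that("incremental deltas are additive across the comparison chain", {
  fit <- cea_model(table1)
  cmp <- fit$comparisons
  key <- function(i, r) which(cmp$intervention == i & cmp$reference == r)
  for (col in c("delta_cost", "delta_ly", "delta_qaly")) {
    expect_equal(cmp[key("lecanemab", "aducanumab"), col],
                 cmp[key("lecanemab", "soc"), col] - cmp[key("aducanumab", "soc"), col],
                 tolerance = 1e-9)
  }
})

test_that("a null intervention priced at reference levels has exactly zero deltas", {
  p <- nullify_intervention(table1, "lecanemab")
  cmp <- manual_comparison(p, "lecanemab", "soc")
  expect_identical(cmp$delta_cost, 0)
  expect_identical(cmp$delta_qaly, 0)
  expect_identical(cmp$delta_ly, 0)

  inst <- generate_instance(seed = 11, effect_hr = 1, drug_price = 0)
  inst$strategies$intervention$admin_annual <- 0
  inst$strategies$intervention$aria_annual <- inst$strategies$soc$aria_annual
  cmp2 <- manual_comparison(inst, "intervention", "soc")
  expect_equal(cmp2$delta_cost, 0)
  expect_equal(cmp2$delta_qaly, 0)
})

test_that("outcomes respond monotonically to unit costs and utilities", {
  base <- cea_model(table1)$results$lecanemab
  for (nm in c("cost.outpatient", "cost.inpatient",
               "strategy.lecanemab.admin_annual", "strategy.lecanemab.price")) {
    up <- cea_model(set_param(table1, nm, get_param(table1, nm) * 1.1))
    expect_gt(up$results$lecanemab$cost, base$cost)
  }
  for (nm in paste0("utility.", alive_states())) {
    up <- cea_model(set_param(table1, nm, min(1, get_param(table1, nm) + 0.02)))
    expect_gt(up$results$lecanemab$qaly, base$qaly)
  }
})

test_that("value-based price solves the threshold relationship exactly", {
  p <- table1
  fit <- cea_model(p)
  cmp <- fit$comparisons
  icer <- cmp$icer_per_qaly[cmp$intervention == "lecanemab" & cmp$reference == "soc"]

  # fixed point: at the base-case ICER the solution is the list price
  expect_equal(value_based_price(p, "lecanemab", "soc", icer), 26500,
               tolerance = 1e-6)

  vbp0 <- value_based_price(p, "lecanemab", "soc", 0)
  vbp150 <- value_based_price(p, "lecanemab", "soc", 150000)
  vbp300 <- value_based_price(p, "lecanemab", "soc", 300000)
  expect_lt(vbp150, 26500)
  expect_true(vbp0 < vbp150 && vbp150 < vbp300)  # monotone in WTP

  # verify by re-running the model at the solved price
  p2 <- p
  p2$strategies$lecanemab$drug_price_schedule <- data.frame(from_cycle = 0L, price = vbp150)
  cmp2 <- cea_model(p2)$comparisons
  got <- cmp2$icer_per_qaly[cmp2$intervention == "lecanemab" & cmp2$reference == "soc"]
  expect_equal(got, 150000, tolerance = 1e-6)

  # no finite price when the QALY delta is not positive
  worse <- set_param(p, "strategy.lecanemab.hr", 1.6)
  out <- value_based_price(worse, "lecanemab", "soc", 150000)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "QALY delta")
})
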