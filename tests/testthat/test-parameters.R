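test_that("shipped configuration reproduces the published inputs and validates cleanly", {
  p <- load_parameters(system.file("extdata", "table1_params.yaml", package = "adcea"))

  expect_length(validate_parameters(p), 0)
  expect_equal(p$soc_transitions["MCI", "MILD"], 0.32)
  expect_equal(p$soc_transitions["MILD", "MODERATE"], 0.36)
  expect_equal(p$soc_transitions["MODERATE", "MCI"], 0)
  expect_equal(unname(p$utilities["MCI"]), 0.73)
  expect_equal(p$mortality$age_bands$rate, c(0.02, 0.05, 0.16))
  expect_equal(unname(p$mortality$stage_hr["SEVERE"]), 9.52)
  expect_equal(p$costs$inpatient, 17935.84)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(get_param(p, "strategy.lecanemab.price"), 26500)
  expect_equal(p$strategies$aducanumab$drug_price_schedule$price, c(20500, 28200))
  expect_equal(get_param(p, "strategy.lecanemab.hr"), 0.69)
  expect_equal(get_param(p, "strategy.aducanumab.hr.MCI.MILD"), 0.83)
  # unlisted transitions keep hazard ratio 1
  expect_equal(get_param(p, "strategy.aducanumab.hr.MILD.MODERATE"), 1)

  # utilities are monotone non-increasing with severity in the shipped set
  expect_true(all(diff(p$utilities[alive_states()]) <= 0))

  # OSA ranges mirror the printed limit columns
  expect_equal(p$osa_ranges[["utility.MILD"]], c(0.55, 0.83))
  expect_equal(p$osa_ranges[["discount.lecanemab_group"]], c(0, 0.08))
  expect_equal(p$osa_ranges[["cost.inpatient"]], c(14348.67, 21523.01))

  # identical to the in-code constructor
  expect_equal(p, table1, tolerance = 1e-9)
})

test_that("parameter files round-trip field-for-field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(table1, path)
  expect_equal(load_parameters(path), table1, tolerance = 1e-9)

  inst <- generate_instance(seed = 7)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(inst, path2)
  back <- load_parameters(path2)
  expect_equal(back$soc_transitions, inst$soc_transitions, tolerance = 1e-9)
  expect_equal(back$strategies$intervention$hr_progression,
               inst$strategies$intervention$hr_progression, tolerance = 1e-9)
})

test_that("loading reports missing keys by name", {
  y <- yaml::read_yaml(system.file("extdata", "table1_params.yaml", package = "adcea"))
  y$discount_rate <- NULL
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(y, path)
  expect_error(load_parameters(path), "discount_rate")

  y2 <- yaml::read_yaml(system.file("extdata", "table1_params.yaml", package = "adcea"))
  y2$strategies$lecanemab$start_age <- NULL
  yaml::write_yaml(y2, path)
  expect_error(load_parameters(path), "start_age")
})

test_that("validate_parameters names the offending field and rule", {
  expect_length(validate_parameters(table1), 0)

  bad <- set_param(table1, "utility.MCI", 1.2)
  v <- validate_parameters(bad)
  expect_gte(length(v), 1)
  expect_match(v, "utilities.*\\[0,1\\]", all = FALSE)

  bad2 <- table1
  bad2$soc_transitions["MCI", c("MILD", "MODERATE", "SEVERE")] <- c(0.6, 0.5, 0.1)
  v2 <- validate_parameters(bad2)
  expect_match(v2, "soc_transitions\\[MCI,\\]", all = FALSE)
  expect_match(v2, "sum", all = FALSE)

  bad3 <- table1
  bad3$strategies$lecanemab$start_distribution <- c(MCI = 0.7, MILD = 0.7)
  expect_match(validate_parameters(bad3), "start_distribution", all = FALSE)

  bad4 <- table1
  bad4$osa_ranges[["no.such.param"]] <- c(0, 1)
  expect_match(validate_parameters(bad4), "no.such.param", all = FALSE)
})

test_that("PSA standard errors resolve to the reported value or mean/10", {
  expect_equal(resolve_psa_se(list(family = "beta", mean = 0.73, se = 0.02)), 0.02)
  expect_equal(resolve_psa_se(list(family = "lognormal", mean = 0.69)), 0.069)
  expect_equal(resolve_psa_se(list(family = "fixed", mean = 26500)), 0)
})

test_that("dotted-path resolver reads and writes every advertised family of paths", {
  p <- table1
  expect_equal(get_param(p, "transition.MODERATE.SEVERE"), 0.40)
  expect_equal(get_param(p, "mortality.rate.85plus"), 0.16)
  expect_equal(get_param(p, "mortality.hr.MILD"), 2.92)
  expect_equal(get_param(p, "cost.outpatient"), 3237.26)
  expect_equal(get_param(p, "start_age.soc_group"), 71.0)
  expect_equal(get_param(p, "discount.lecanemab_group"), 0.03)

  p2 <- set_param(p, "strategy.aducanumab.price", 16400)
  expect_equal(p2$strategies$aducanumab$drug_price_schedule$price,
               c(16400, 28200 * 16400 / 20500))

  p3 <- set_param(p, "strategy.lecanemab.hr", 0.5)
  expect_equal(unname(p3$strategies$lecanemab$hr_progression),
               c(0.5, 0.5))

  p4 <- set_param(p, "discount.lecanemab_group", 0)
  expect_equal(p4$strategies$lecanemab$discount_rate, 0)
  expect_equal(p4$strategies$aducanumab$discount_rate, 0)
  expect_null(p4$strategies$soc$discount_rate)

  p5 <- set_param(p, "strategy.soc.start_mci", 0.662)
  expect_equal(unname(p5$strategies$soc$start_distribution),
               c(0.662, 0.338))

  expect_error(get_param(p, "strategy.lecanemab.bogus"), "unresolvable")
  expect_error(get_param(p, "utility.GONE"), "unknown state")
})

test_that("audit table covers every sensitivity parameter with value, se and limits", {
  aud <- params_audit(table1)
  expect_true(all(union(names(table1$psa_distributions),
                        names(table1$osa_ranges)) %in% aud$name))
  mild <- aud[aud$name == "utility.MILD", ]
  expect_equal(mild$value, 0.69)
  expect_equal(mild$se, 0.01)
  expect_equal(c(mild$low, mild$high), c(0.55, 0.83))
  expect_equal(mild$family, "beta")
  inp <- aud[aud$name == "cost.inpatient", ]
  expect_equal(inp$se, 1145.99)
})
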