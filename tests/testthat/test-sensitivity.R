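test_that("moment matching hits the published means and spreads", {
  b <- adcea:::match_beta(0.73, 0.02)
  expect_equal(unname(b), c(358.9775, 132.7725), tolerance = 1e-9)
  g <- adcea:::match_gamma(17935.84, 1145.99)
  expect_equal(unname(g[["shape"]]), 244.952449, tolerance = 1e-6)
  ln <- adcea:::match_lognormal(0.69, 0.069)
  # mean of the matched lognormal equals the base value
  expect_equal(exp(ln[["meanlog"]] + ln[["sdlog"]]^2 / 2), 0.69, tolerance = 1e-12)

  set.seed(404)
  expect_equal(mean(stats::rbeta(1e5, b[["shape1"]], b[["shape2"]])), 0.73,
               tolerance = 1.5e-3)
  expect_equal(mean(stats::rgamma(1e5, shape = g[["shape"]], scale = g[["scale"]])),
               17935.84, tolerance = 0.005 * 17935.84)
  expect_equal(mean(stats::rlnorm(1e5, ln[["meanlog"]], ln[["sdlog"]])), 0.69,
               tolerance = 1.5e-3)

  expect_error(adcea:::match_beta(0.5, 0.6), "infeasible")
})

test_that("PSA draws are valid, centred on the base case, and leave fixed inputs alone", {
  set.seed(42)
  base <- table1
  draws <- replicate(300, {
    d <- draw_parameters(base)
    expect_length(validate_parameters(d), 0)
    # fixed in every draw: drug prices and band mortality
    expect_equal(d$strategies$lecanemab$drug_price_schedule$price, 26500)
    expect_equal(d$strategies$aducanumab$drug_price_schedule$price, c(20500, 28200))
    expect_equal(d$mortality$age_bands$rate, c(0.02, 0.05, 0.16))
    # the two lecanemab progression HRs share one draw
    hrs <- d$strategies$lecanemab$hr_progression
    expect_equal(unname(hrs[1]), unname(hrs[2]))
    c(hr = unname(hrs[1]), u = unname(d$utilities["MILD"]),
      inp = d$costs$inpatient)
  })
  # sample means converge to the deterministic values (~1/sqrt(n))
  expect_equal(mean(draws["hr", ]), 0.69, tolerance = 3 * 0.069 / sqrt(300) / 0.69)
  expect_equal(mean(draws["u", ]), 0.69, tolerance = 3 * 0.01 / sqrt(300) / 0.69)
  expect_equal(mean(draws["inp", ]), 17935.84, tolerance = 3 * 1145.99 / sqrt(300) / 17935.84)
  # utilities stayed in (0,1), costs positive
  expect_true(all(draws["u", ] > 0 & draws["u", ] < 1))
  expect_true(all(draws["inp", ] > 0))
})

test_that("PSA is reproducible from its seed and collapses under degenerate SEs", {
  p1 <- run_psa(table1, n_draws = 5, seed = 123)
  p2 <- run_psa(table1, n_draws = 5, seed = 123)
  expect_identical(p1$samples, p2$samples)

  deg <- degenerate_psa(table1)
  pd <- run_psa(deg, n_draws = 4, seed = 9)
  for (i in seq_len(nrow(pd$samples))) {
    j <- which(pd$base$intervention == pd$samples$intervention[i] &
                 pd$base$reference == pd$samples$reference[i])
    expect_equal(pd$samples$delta_cost[i], pd$base$delta_cost[j])
    expect_equal(pd$samples$delta_qaly[i], pd$base$delta_qaly[j])
  }
})

test_that("CEAC probabilities follow net monetary benefit and locate the base ICER", {
  # hand-made samples: dominant draws are cost-effective everywhere
  s <- data.frame(draw = 1:4, intervention = "a", reference = "b",
                  delta_cost = c(-10, -5, -1, -2), delta_ly = 1,
                  delta_qaly = c(0.1, 0.2, 0.3, 0.4))
  cc <- ceac(s, wtp_grid = c(0, 1000, 2000))
  expect_equal(cc$probability, rep(1, 3))

  # lambda = 0 counts the cost-saving fraction
  s2 <- s
  s2$delta_cost <- c(-10, 5, -1, 2)
  expect_equal(ceac(s2, wtp_grid = 0)$probability, 0.5)

  # degenerate PSA: step function at the base-case ICER
  deg <- degenerate_psa(table1)
  pd <- run_psa(deg, n_draws = 2, seed = 1)
  cc2 <- ceac(pd, wtp_grid = seq(0, 2e6, by = 1e4))
  base_icer <- pd$base$icer_per_qaly[pd$base$intervention == "lecanemab" &
                                       pd$base$reference == "soc"]
  curve <- cc2[cc2$intervention == "lecanemab" & cc2$reference == "soc", ]
  expect_true(all(curve$probability[curve$wtp < base_icer - 1e4] == 0))
  expect_true(all(curve$probability[curve$wtp > base_icer + 1e4] == 1))
  cross <- ceac_crossing(curve)
  expect_lt(abs(cross - base_icer), 1e4 + 1e-6)

  # monotone whenever every sampled QALY delta is positive
  expect_true(all(diff(curve$probability) >= 0))

  # level never reached
  flat <- data.frame(draw = 1:2, intervention = "a", reference = "b",
                     delta_cost = c(10, 20), delta_ly = 1, delta_qaly = c(-0.1, -0.2))
  cf <- ceac(flat, wtp_grid = c(0, 1e4))
  out <- ceac_crossing(cf, level = 0.5)
  expect_true(is.na(out))
  expect_equal(attr(out, "max_probability"), 0)
  # level 0 is met at the grid minimum
  expect_equal(ceac_crossing(cf, level = 0), 0)
})

test_that("per-draw deltas are additive across comparisons sharing the reference arm", {
  psa <- run_psa(table1, n_draws = 25, seed = 77)
  s <- psa$samples
  for (d in unique(s$draw)) {
    sd <- s[s$draw == d, ]
    la <- sd[sd$intervention == "lecanemab" & sd$reference == "aducanumab", ]
    ls <- sd[sd$intervention == "lecanemab" & sd$reference == "soc", ]
    as <- sd[sd$intervention == "aducanumab" & sd$reference == "soc", ]
    expect_equal(la$delta_cost, ls$delta_cost - as$delta_cost, tolerance = 1e-9)
    expect_equal(la$delta_qaly, ls$delta_qaly - as$delta_qaly, tolerance = 1e-9)
  }
})

test_that("tornado entries are independently reproducible and degenerate ranges collapse", {
  p <- table1
  p$osa_ranges <- p$osa_ranges[c("utility.MILD", "strategy.lecanemab.price",
                                 "transition.MCI.SEVERE", "discount.lecanemab_group")]
  tor <- one_way_sensitivity(p, c("lecanemab", "aducanumab"))
  expect_setequal(tor$parameter, names(p$osa_ranges))
  expect_true(all(diff(tor$spread) <= 0))

  # spot-reproduce each bound by an independent full model run
  for (i in seq_len(nrow(tor))) {
    nm <- tor$parameter[i]
    for (side in c("low", "high")) {
      val <- tor[[paste0(side, "_input")]][i]
      fit <- cea_model(set_param(p, nm, val))
      cmp <- fit$comparisons
      got <- cmp$icer_per_qaly[cmp$intervention == "lecanemab" &
                                 cmp$reference == "aducanumab"]
      expect_equal(got, tor[[paste0("icer_", side)]][i], tolerance = 1e-12)
    }
  }

  # equal limits give zero spread; discount varied jointly stays finite
  expect_equal(tor$spread[tor$parameter == "transition.MCI.SEVERE"], 0)
  drow <- tor[tor$parameter == "discount.lecanemab_group", ]
  expect_true(is.finite(drow$icer_low) && is.finite(drow$icer_high))

  # an invalid limit is skipped with a warning naming the parameter
  p$osa_ranges[["utility.MCI"]] <- c(0.58, 1.2)
  expect_warning(one_way_sensitivity(p, c("lecanemab", "aducanumab")),
                 "utility.MCI")
})
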