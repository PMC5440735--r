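test_that("constant annualization scales 4-week quantities by 365.25/28", {
  expect_equal(annualize_constant(0), 0)
  expect_equal(annualize_constant(13.0), 13.0 * 365.25 / 28, tolerance = 1e-12)
  expect_equal(annualize_constant(13.0), 169.6, tolerance = 1e-3)
  expect_equal(annualize_constant(2.073), 27.04, tolerance = 1e-3)
  expect_error(annualize_constant(-1), "non-negative")
})

test_that("PFMT annualization applies the arm-specific maintenance blend", {
  ctl <- annualization_policy("control")
  app <- annualization_policy("app")
  expect_equal(annualize_pfmt(0, ctl), 0)
  expect_equal(annualize_pfmt(0, app), 0)
  expect_equal(annualize_pfmt(0.7597, ctl), 9.91, tolerance = 1e-3)
  # hand evaluation: 4.0 * 13.045 * (0.25 + 0.75 * 2.5/21)
  expect_equal(annualize_pfmt(4.0, app),
               4.0 * (365.25 / 28) * (0.25 + 0.75 * 2.5 / 21),
               tolerance = 1e-12)
  expect_equal(annualize_pfmt(4.0, app), 17.70, tolerance = 1e-2)
  # monotone in the maintenance fraction: full maintenance == control rate,
  # zero maintenance = treatment fraction only
  h <- 3.7
  full <- annualization_policy("app", sessions_per_week_maintenance = 21)
  low <- annualization_policy("app", sessions_per_week_maintenance = 1e-9)
  expect_lte(annualize_pfmt(h, app), annualize_pfmt(h, full))
  expect_gte(annualize_pfmt(h, app), annualize_pfmt(h, low))
  expect_equal(annualize_pfmt(h, full), annualize_pfmt(h, ctl))
})

test_that("time and goods costs use wages and unit prices", {
  prices <- price_config()
  expect_equal(time_cost(15.66, "university", prices), 463.7, tolerance = 0.05)
  expect_equal(time_cost(3.38, "university", prices), 100.1, tolerance = 0.05)
  expect_equal(time_cost(0, "other", prices), 0)
  expect_error(time_cost(1, "postgrad", prices), "postgrad")
  expect_equal(goods_cost(10.40, 2.21), 23.0, tolerance = 0.02)
  expect_equal(goods_cost(169.60, 0.134), 22.7, tolerance = 0.03)
  expect_equal(goods_cost(0, 2.21), 0)
})

test_that("arm-mean amounts reproduce the published totals", {
  am <- table2_amounts()
  app <- cost_breakdown_from_amounts(am$app[["pfmt_hours"]],
                                     am$app[["laundry_hours"]],
                                     am$app[["aids"]],
                                     am$app[["laundry_loads"]])
  ctl <- cost_breakdown_from_amounts(am$control[["pfmt_hours"]],
                                     am$control[["laundry_hours"]],
                                     am$control[["aids"]],
                                     am$control[["laundry_loads"]])
  expect_equal(app$total, 547.0, tolerance = 0.2 / 547)
  expect_equal(ctl$total, 482.4, tolerance = 0.2 / 482.4)
  expect_equal(app$treatment_delivery, 0)
  expect_equal(ctl$treatment_delivery, 0)
  # all-zero resource use costs exactly the assessment
  zero <- cost_breakdown_from_amounts(0, 0, 0, 0)
  expect_equal(zero$total, price_config()$assessment_cost)
})

test_that("cost breakdowns are additive and homogeneous", {
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- stats::runif(4, 0, 200)
      bd <- cost_breakdown(assessment = x[1], pfmt_time = x[2],
                           laundry_time = x[3], aids = x[4])
      expect_equal(bd$total,
                   bd$assessment + bd$treatment_delivery + bd$pfmt_time +
                     bd$laundry_time + bd$aids + bd$laundry_loads,
                   tolerance = 1e-9)
    }
    # doubling all unit prices (incl. assessment) doubles the total
    am <- table2_amounts()$app
    p1 <- price_config()
    p2 <- price_config(assessment_cost = 2 * p1$assessment_cost,
                       wage_by_education = 2 * p1$wage_by_education,
                       aid_unit_price = 2 * p1$aid_unit_price,
                       laundry_load_price = 2 * p1$laundry_load_price)
    b1 <- cost_breakdown_from_amounts(am[["pfmt_hours"]], am[["laundry_hours"]],
                                      am[["aids"]], am[["laundry_loads"]],
                                      prices = p1)
    b2 <- cost_breakdown_from_amounts(am[["pfmt_hours"]], am[["laundry_hours"]],
                                      am[["aids"]], am[["laundry_loads"]],
                                      prices = p2)
    expect_equal(b2$total, 2 * b1$total, tolerance = 1e-12)
  })
})

test_that("participant-level costing annualizes, values, and averages by arm", {
  df <- tibble::tibble(
    participant_id = c("a1", "a2", "c1"),
    arm = c("app", "app", "control"),
    education = c("university", "other", "university"),
    pfmt_hours_4wk = c(4, 0, 0.7597),
    laundry_hours_4wk = c(0.1, 0, 0.2591),
    aids_4wk = c(8, 0, 13),
    laundry_loads_4wk = c(1, 0, 2.073))
  out <- total_annual_cost(df)
  expect_equal(out$pfmt_hours_yr[1], annualize_pfmt(4, annualization_policy("app")))
  expect_equal(out$pfmt_hours_yr[3], annualize_pfmt(0.7597, annualization_policy("control")))
  expect_equal(out$total[2], 6.4) # zero resource use: assessment only
  expect_equal(out$total,
               out$assessment + out$pfmt_time + out$laundry_time +
                 out$aids_cost + out$laundry_loads_cost, tolerance = 1e-9)
  summ <- arm_cost_summary(out)
  expect_equal(summ$total[summ$arm == "app"], mean(out$total[1:2]))
  bd <- as_cost_breakdown(summ[summ$arm == "control", ])
  expect_s3_class(bd, "cost_breakdown")
  expect_equal(bd$total, out$total[3])
  expect_error(total_annual_cost(df[, -4]), "pfmt_hours_4wk")
})

test_that("price config round-trips through YAML", {
  p <- read_price_config(system.file("extdata", "prices.yaml",
                                     package = "trialcua"))
  expect_equal(p$assessment_cost, 6.4)
  expect_equal(unname(p$wage_by_education["university"]), 29.61)
  expect_equal(p$aid_unit_price, 0.134)
  expect_equal(p$laundry_load_price, 2.21)
  expect_equal(p$sek_per_eur, 8.94)
})
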