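test_that("scenario application scales, excludes, and leaves the rest bit-identical", {
  bds <- table2_breakdowns()
  halved <- apply_scenario(bds$app, default_scenarios()$pfmt_time_halved)
  expect_equal(halved$total, 315.1, tolerance = 0.2 / 315.1)
  expect_identical(halved$laundry_time, bds$app$laundry_time)
  expect_identical(halved$aids, bds$app$aids)
  no_laundry_time <- apply_scenario(bds$app,
                                    default_scenarios()$laundry_time_excluded)
  expect_equal(no_laundry_time$total, 508.5, tolerance = 1e-9) # 547.0 - 38.5
  expect_equal(no_laundry_time$laundry_time, 0)
  # empty scenario is the identity
  empty <- scenario("noop", tibble::tibble(component = character(),
                                           action = character(),
                                           factor = numeric()))
  expect_equal(apply_scenario(bds$app, empty), bds$app)
  expect_error(scenario("bad", tibble::tibble(component = "rent",
                                              action = "scale", factor = 0.5)),
               "rent")
  expect_error(scenario("bad", tibble::tibble(component = "aids",
                                              action = "scale", factor = -1)),
               "positive factor")
})

test_that("scenario algebra: composition, exclude-as-zero, idempotence", {
  bd <- table2_breakdowns()$control
  sa <- scenario("a", tibble::tibble(component = "pfmt_time", action = "scale",
                                     factor = 0.6))
  sb <- scenario("b", tibble::tibble(component = "pfmt_time", action = "scale",
                                     factor = 0.5))
  sab <- scenario("ab", tibble::tibble(component = "pfmt_time",
                                       action = "scale", factor = 0.3))
  expect_equal(apply_scenario(apply_scenario(bd, sa), sb),
               apply_scenario(bd, sab))
  excl <- scenario("x", tibble::tibble(component = "laundry_time",
                                       action = "exclude", factor = NA))
  zero <- scenario("z", tibble::tibble(component = "laundry_time",
                                       action = "scale", factor = 1e-300))
  once <- apply_scenario(bd, excl)
  expect_equal(apply_scenario(once, excl), once) # idempotent
  expect_equal(apply_scenario(bd, zero)$total, once$total, tolerance = 1e-9)
  # one-way scale of component c by f changes the total by (f-1)*c
  f <- 0.37
  sc <- scenario("s", tibble::tibble(component = "aids", action = "scale",
                                     factor = f))
  expect_equal(apply_scenario(bd, sc)$total - bd$total, (f - 1) * bd$aids,
               tolerance = 1e-9)
})

test_that("the four standard scenarios reproduce the published sensitivity table", {
  bds <- table2_breakdowns()
  gains <- table3_qaly_gains()
  tab <- run_sensitivity(bds$app, bds$control, gains[["app"]],
                         gains[["control"]])
  expect_equal(tab$scenario[1], "base")
  want <- tibble::tibble(
    scenario = c("base", "pfmt_time_halved", "laundry_cost_halved",
                 "laundry_time_excluded", "multiway"),
    app_total = c(547.0, 315.1, 535.4, 508.5, 265.1),
    control_total = c(482.4, 335.7, 452.4, 382.3, 205.7),
    icer = c(7615.5, -2425.7, 9785.5, 14870.6, 6999.5))
  got <- tab[match(want$scenario, tab$scenario), ]
  expect_equal(got$app_total, want$app_total, tolerance = 0.2 / 300)
  expect_equal(got$control_total, want$control_total, tolerance = 0.2 / 300)
  expect_equal(got$icer, want$icer, tolerance = 0.002)
  expect_equal(got$quadrant, c("NE", "SE", "NE", "NE", "NE"))
  # cost-side only: QALY entries never altered by scenarios
  expect_true(all(tab$app_qaly_gain == gains[["app"]]))
  expect_true(all(tab$control_qaly_gain == gains[["control"]]))
  expect_true(all(tab$delta_qaly == gains[["app"]] - gains[["control"]]))
  # the ICER range spans a sign change exactly when some dCost < 0
  expect_equal(any(tab$delta_cost < 0),
               min(tab$icer) < 0 && max(tab$icer) > 0)
})

test_that("scenarios scaling a zero-valued component leave the row at base", {
  bd <- cost_breakdown(assessment = 6.4, pfmt_time = 100, laundry_time = 0,
                       aids = 10, laundry_loads = 5)
  sc <- scenario("s", tibble::tibble(component = "laundry_time",
                                     action = "scale", factor = 0.5))
  expect_equal(apply_scenario(bd, sc), bd)
})

test_that("bundled scenario file matches the built-in defaults", {
  path <- system.file("extdata", "scenarios.yaml", package = "trialcua")
  fromfile <- read_scenarios(path)
  defaults <- default_scenarios()
  expect_equal(names(fromfile), names(defaults))
  for (nm in names(defaults)) {
    expect_equal(fromfile[[nm]]$modifications, defaults[[nm]]$modifications)
  }
})
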