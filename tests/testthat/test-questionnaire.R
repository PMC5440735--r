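test_that("LUTSqol scoring sums item levels over the 19-76 range", {
  expect_equal(score_lutsqol(make_response(1))$lutsqol_total, 19)
  expect_equal(score_lutsqol(make_response(4))$lutsqol_total, 76)
  # ten items at level 2, nine at level 1, hand-summed
  resp <- make_response(c(rep(2, 10), rep(1, 9)))
  expect_equal(score_lutsqol(resp)$lutsqol_total, 29)
})

test_that("LUTSqol validation names the offending item", {
  bad <- make_response(1)
  bad$item07 <- 5
  expect_error(score_lutsqol(bad), "item07")
  gone <- make_response(1)[, -3] # drop item03
  expect_error(score_lutsqol(gone), "item03")
  miss <- make_response(1)
  miss$item12 <- NA
  expect_error(score_lutsqol(miss), "item12")
  expect_true(is.na(score_lutsqol(miss, na_action = "omit")$lutsqol_total))
})

test_that("UI SF scoring sums the three items over 0-21", {
  expect_equal(score_uisf(make_response(1, c(0, 0, 0)))$uisf_total, 0)
  expect_equal(score_uisf(make_response(1, c(5, 6, 10)))$uisf_total, 21)
  expect_equal(score_uisf(make_response(1, c(3, 4, 4)))$uisf_total, 11)
  bad <- make_response(1, c(6, 0, 0)) # frequency capped at 5
  expect_error(score_uisf(bad), "uisf_freq")
})

test_that("severity bands follow the published cut points, 0 labelled none", {
  expect_equal(as.character(severity_band(c(0, 1, 5, 6, 11, 12, 13, 18, 19, 21))),
               c("none", "slight", "slight", "moderate", "moderate", "moderate",
                 "severe", "severe", "very severe", "very severe"))
  expect_error(severity_band(22), "\\[0, 21\\]")
  expect_error(severity_band(-1), "\\[0, 21\\]")
  df <- categorize_severity(tibble::tibble(uisf_total = c(0, 11)))
  expect_s3_class(df$severity, "ordered")
  expect_equal(as.character(df$severity), c("none", "moderate"))
})

test_that("health-state classification projects the 9 selected items in config order", {
  cfg <- default_utility_config()
  hs <- classify_health_state(make_response(1), cfg)
  expect_equal(names(hs), cfg$selected_items)
  expect_true(all(hs == 1))
  # cycling levels: selected levels must match a per-item dictionary lookup
  resp <- make_response(rep(1:4, length.out = 19))
  lookup <- setNames(rep(1:4, length.out = 19), lutsqol_items())
  hs2 <- classify_health_state(resp, cfg)
  expect_equal(unlist(hs2[1, ]), lookup[cfg$selected_items])
  # config selecting an item the response lacks
  cfg2 <- cfg
  cfg2$selected_items[1] <- "item99"
  rownames(cfg2$decrements)[1] <- "item99"
  expect_error(classify_health_state(resp, cfg2), "item99")
})

test_that("utility weight is base minus additive decrements, clamped", {
  items <- lutsqol_items()[1:9]
  dec0 <- matrix(0, 9, 4)
  cfg <- utility_index_config(items, base_value = 1.0, decrements = dec0)
  expect_equal(utility_from_levels(rep(1, 9), cfg), 1.0)
  # decrements summing past the floor clamp at 0
  dec_big <- matrix(rep(c(0, 0, 0, 0.15), each = 9), 9, 4)
  cfg_big <- utility_index_config(items, 1.0, dec_big, clamp_floor = 0)
  expect_equal(utility_from_levels(rep(4, 9), cfg_big), 0) # 1 - 1.35 clamped
  # hand subtraction: base 0.95, two active decrements 0.02 and 0.01
  dec <- matrix(0, 9, 4)
  dec[1, 2:4] <- 0.02
  dec[2, 2:4] <- 0.01
  cfg3 <- utility_index_config(items, 0.95, dec)
  expect_equal(utility_from_levels(c(2, 2, rep(1, 7)), cfg3), 0.92)
  expect_error(utility_index_config(items, 0.95, dec - 0.001), "non-negative")
})

test_that("utility weight is monotone and bounded for random responses", {
  cfg <- default_utility_config()
  withr::with_seed(7, {
    resp <- random_responses(100)
    scored <- utility_weight(score_lutsqol(resp), cfg)
    expect_true(all(scored$lutsqol_total >= 19 & scored$lutsqol_total <= 76))
    expect_true(all(scored$utility >= 0 & scored$utility <= 1))
    # raising any single selected item never increases the utility
    for (i in 1:25) {
      row <- scored[sample(nrow(scored), 1), ]
      it <- sample(cfg$selected_items, 1)
      if (row[[it]] < 4) {
        worse <- row
        worse[[it]] <- row[[it]] + 1
        expect_lte(utility_weight(worse, cfg)$utility, row$utility)
      }
    }
    # scoring is permutation-invariant: shuffle each row's levels across items
    perm <- sample(lutsqol_items())
    shuffled <- resp
    shuffled[lutsqol_items()] <- resp[perm]
    expect_equal(score_lutsqol(shuffled)$lutsqol_total,
                 score_lutsqol(resp)$lutsqol_total)
  })
})

test_that("utility config round-trips through YAML", {
  path <- system.file("extdata", "utility_index_synthetic.yaml",
                      package = "trialcua")
  cfg <- read_utility_config(path)
  def <- default_utility_config()
  expect_equal(cfg$selected_items, def$selected_items)
  expect_equal(unname(cfg$decrements), unname(def$decrements))
  expect_equal(cfg$base_value, def$base_value)
})
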