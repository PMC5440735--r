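# Shared fixtures and independent oracles.

# One questionnaire response as a one-row tibble; `levels` recycles over
# the 19 LUTSqol items.
make_response <- function(levels = 1, uisf = c(0, 0, 0)) {
  lv <- rep(levels, length.out = 19)
  out <- tibble::as_tibble(as.list(stats::setNames(lv, lutsqol_items())))
  out$uisf_freq <- uisf[1]
  out$uisf_amount <- uisf[2]
  out$uisf_impact <- uisf[3]
  out
}

# n random valid responses under the local RNG state.
random_responses <- function(n) {
  m <- matrix(sample(1:4, n * 19, replace = TRUE), nrow = n)
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- lutsqol_items()
  out$uisf_freq <- sample(0:5, n, replace = TRUE)
  out$uisf_amount <- sample(0:6, n, replace = TRUE)
  out$uisf_impact <- sample(0:10, n, replace = TRUE)
  out
}

# Brute-force AUC oracle: numerical integration of the interpolated curve
# on a 1e-4-yr grid (augmented with the assessment times so no cell strides
# a kink), with constant extension beyond the last assessment. Independent
# of qaly_auc().
riemann_auc <- function(times, utilities, horizon, step = 1e-4) {
  xs <- sort(unique(c(seq(0, horizon, by = step), times, horizon)))
  mid <- (head(xs, -1) + tail(xs, -1)) / 2
  vals <- stats::approx(times, utilities, xout = pmin(mid, max(times)),
                        rule = 2)$y
  sum(vals * diff(xs))
}

# Arm-mean annual amounts as printed in the published cost table.
table2_amounts <- function() {
  list(app = c(pfmt_hours = 15.66, laundry_hours = 1.30,
               aids = 114.40, laundry_loads = 10.40),
       control = c(pfmt_hours = 9.91, laundry_hours = 3.38,
                   aids = 169.60, laundry_loads = 27.04))
}

# Arm breakdowns at the published component-cost precision (0.1 EUR).
table2_breakdowns <- function() {
  list(app = cost_breakdown(assessment = 6.4, treatment_delivery = 0,
                            pfmt_time = 463.7, laundry_time = 38.5,
                            aids = 15.4, laundry_loads = 23.0),
       control = cost_breakdown(assessment = 6.4, treatment_delivery = 0,
                                pfmt_time = 293.4, laundry_time = 100.1,
                                aids = 22.7, laundry_loads = 59.8))
}

table3_qaly_gains <- function() c(app = 0.01006, control = 0.00158)
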