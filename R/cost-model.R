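#' Unit prices and wages for the societal cost model
#'
#' All prices in 2013 year-end euro (the study's fixed conversion is
#' 1 EUR = 8.94 SEK). Participant time is valued at the gross hourly wage of
#' women with the same educational level; the default wage table carries the
#' cohort-level mean wage for both strata and is meant to be overridden with
#' stratified wages where available.
#'
#' @param assessment_cost Euro per participant for assessment (mailing the
#'   leakage diary and administrator time), default 6.4.
#' @param wage_by_education Named euro-per-hour lookup over education strata.
#' @param aid_unit_price Euro per incontinence aid, default 0.134.
#' @param laundry_load_price Euro per extra laundry load, default 2.21.
#' @param currency Currency label.
#' @param sek_per_eur Fixed 2013 exchange rate, kept as metadata.
#' @return Object of class `price_config`.
#' @export
price_config <- function(assessment_cost = 6.4,
                         wage_by_education = c(university = 29.61, other = 29.61),
                         aid_unit_price = 0.134,
                         laundry_load_price = 2.21,
                         currency = "EUR (2013 year-end)",
                         sek_per_eur = 8.94) {
  vals <- c(assessment_cost, wage_by_education, aid_unit_price,
            laundry_load_price)
  if (any(vals < 0)) abort("all prices and wages must be non-negative")
  if (is.null(names(wage_by_education)) || any(names(wage_by_education) == "")) {
    abort("wage_by_education must be a named vector keyed by education stratum")
  }
  structure(
    list(assessment_cost = assessment_cost,
         wage_by_education = wage_by_education,
         aid_unit_price = aid_unit_price,
         laundry_load_price = laundry_load_price,
         currency = currency, sek_per_eur = sek_per_eur),
    class = "price_config"
  )
}

#' Read a price configuration from YAML or JSON
#' @param path File path; keys mirror the arguments of [price_config()].
#' @return A `price_config`.
#' @export
read_price_config <- function(path) {
  raw <- yaml::read_yaml(path)
  price_config(
    assessment_cost = as.numeric(raw$assessment_cost),
    wage_by_education = unlist(raw$wage_by_education),
    aid_unit_price = as.numeric(raw$aid_unit_price),
    laundry_load_price = as.numeric(raw$laundry_load_price),
    currency = raw$currency %||% "EUR (2013 year-end)",
    sek_per_eur = as.numeric(raw$sek_per_eur %||% 8.94)
  )
}

#' Arm-specific annualization policy for training time
#'
#' Resource use is self-reported over the last 4 weeks at the 3-month
#' follow-up. For the untreated arm the reported rate is assumed constant
#' over the year. For the app arm, the reported rate reflects the active
#' treatment prescription (3 sessions/day); after the 3-month treatment the
#' prescription drops to maintenance training (2-3 sessions/week), so annual
#' hours are scaled by the session-ratio blend
#' \deqn{f + (1 - f)\,m, \quad f = \mathrm{months}/12,\;
#'       m = \mathrm{maintenance\ rate}/\mathrm{treatment\ rate}.}
#'
#' @param arm `"app"` or `"control"`.
#' @param treatment_months Active-treatment duration in months (default 3).
#' @param sessions_per_week_treatment Prescribed sessions per week during
#'   treatment (default 21, i.e. 3/day).
#' @param sessions_per_week_maintenance Prescribed maintenance sessions per
#'   week (default 2.5, the midpoint of "2 or 3").
#' @param weeks_per_year Weeks per year (default 365.25/7); the 4-week to
#'   annual factor is `weeks_per_year / 4` (about 13.045).
#' @return Object of class `annualization_policy`.
#' @export
annualization_policy <- function(arm = c("app", "control"),
                                 treatment_months = 3,
                                 sessions_per_week_treatment = 21,
                                 sessions_per_week_maintenance = 2.5,
                                 weeks_per_year = WEEKS_PER_YEAR) {
  arm <- match.arg(arm)
  if (treatment_months <= 0 || treatment_months > 12) {
    abort("treatment_months must lie in (0, 12]")
  }
  if (sessions_per_week_treatment <= 0 || sessions_per_week_maintenance <= 0) {
    abort("session rates must be positive")
  }
  structure(
    list(arm = arm, treatment_months = treatment_months,
         sessions_per_week_treatment = sessions_per_week_treatment,
         sessions_per_week_maintenance = sessions_per_week_maintenance,
         weeks_per_year = weeks_per_year),
    class = "annualization_policy"
  )
}

#' Default per-arm annualization policies
#' @return Named list with `app` and `control` policies.
#' @export
default_policies <- function() {
  list(app = annualization_policy("app"),
       control = annualization_policy("control"))
}

# maintenance blend factor for an app-arm policy; 1 for control
annualization_blend <- function(policy) {
  if (policy$arm != "app") return(1)
  f <- policy$treatment_months / 12
  m <- policy$sessions_per_week_maintenance / policy$sessions_per_week_treatment
  f + (1 - f) * m
}

#' Annualize 4-week quantities
#'
#' `annualize_constant()` extrapolates any 4-week quantity to a year assuming
#' the follow-up rate stays constant (factor 365.25/28). `annualize_pfmt()`
#' additionally applies the arm-specific maintenance blend of the
#' [annualization_policy()] to pelvic floor muscle training hours.
#'
#' @param quantity_4wk,hours_4wk Non-negative quantity reported over the
#'   last 4 weeks.
#' @param weeks_per_year Weeks per year (default 365.25/7).
#' @param policy An [annualization_policy()].
#' @return Annualized quantity (same units per year).
#' @examples
#' annualize_constant(13.0)                       # ~169.6 aids/yr
#' annualize_pfmt(0.7597, annualization_policy("control")) # ~9.91 h/yr
#' @export
annualize_constant <- function(quantity_4wk, weeks_per_year = WEEKS_PER_YEAR) {
  if (any(quantity_4wk < 0)) abort("4-week quantities must be non-negative")
  quantity_4wk * weeks_per_year / 4
}

#' @rdname annualize_constant
#' @export
annualize_pfmt <- function(hours_4wk, policy) {
  stopifnot(inherits(policy, "annualization_policy"))
  if (any(hours_4wk < 0)) abort("4-week hours must be non-negative")
  hours_4wk * policy$weeks_per_year / 4 * annualization_blend(policy)
}

#' Value participant time and goods in euro
#'
#' @param annual_hours Hours per year.
#' @param education Education stratum, a key of `prices$wage_by_education`.
#' @param prices A [price_config()].
#' @return Euro per year.
#' @export
time_cost <- function(annual_hours, education, prices = price_config()) {
  unknown <- setdiff(unique(education), names(prices$wage_by_education))
  if (length(unknown) > 0) {
    abort(paste0("no wage for education stratum: ",
                 paste(unknown, collapse = ", ")))
  }
  annual_hours * unname(prices$wage_by_education[education])
}

#' @rdname time_cost
#' @param annual_units Units (aids, loads) per year.
#' @param unit_price Euro per unit.
#' @export
goods_cost <- function(annual_units, unit_price) {
  if (any(annual_units < 0) || any(unit_price < 0)) {
    abort("units and prices must be non-negative")
  }
  annual_units * unit_price
}

cost_components <- function() {
  c("assessment", "treatment_delivery", "pfmt_time", "laundry_time",
    "aids", "laundry_loads")
}

#' Construct an annual cost breakdown
#'
#' One row per unit of analysis (participant or arm mean), with the six
#' societal cost components in euro per year and their total. Treatment
#' delivery is identically 0 in this analysis: no costs beyond assessment
#' were identified for delivering the app treatment.
#'
#' @param assessment,treatment_delivery,pfmt_time,laundry_time,aids,laundry_loads
#'   Component costs in euro per year (vectors recycle as in [tibble::tibble()]).
#' @return Tibble of class `cost_breakdown` with the component columns and
#'   `total`.
#' @export
cost_breakdown <- function(assessment, treatment_delivery = 0, pfmt_time = 0,
                           laundry_time = 0, aids = 0, laundry_loads = 0) {
  out <- tibble::tibble(
    assessment = as.numeric(assessment),
    treatment_delivery = as.numeric(treatment_delivery),
    pfmt_time = as.numeric(pfmt_time),
    laundry_time = as.numeric(laundry_time),
    aids = as.numeric(aids),
    laundry_loads = as.numeric(laundry_loads)
  )
  if (any(as.matrix(out) < 0)) abort("cost components must be non-negative")
  out$total <- rowSums(out)
  class(out) <- c("cost_breakdown", class(tibble::tibble()))
  out
}

#' Cost breakdown from annual resource amounts
#'
#' The group-mean entry point: turns annual amounts (hours of training and
#' laundry, aid and laundry-load counts per year — the "Amount used" columns
#' of a published cost table) into a [cost_breakdown()] with the unit prices
#' of `prices`.
#'
#' @param pfmt_hours,laundry_hours Annual hours.
#' @param aids,laundry_loads Annual unit counts.
#' @param education Education stratum for the wage lookup.
#' @param prices A [price_config()].
#' @return A one-row (or recycled) `cost_breakdown`.
#' @examples
#' cost_breakdown_from_amounts(15.66, 1.30, 114.40, 10.40)$total # ~547
#' @export
cost_breakdown_from_amounts <- function(pfmt_hours, laundry_hours, aids,
                                        laundry_loads,
                                        education = "university",
                                        prices = price_config()) {
  cost_breakdown(
    assessment = prices$assessment_cost,
    treatment_delivery = 0,
    pfmt_time = time_cost(pfmt_hours, education, prices),
    laundry_time = time_cost(laundry_hours, education, prices),
    aids = goods_cost(aids, prices$aid_unit_price),
    laundry_loads = goods_cost(laundry_loads, prices$laundry_load_price)
  )
}

#' Per-participant annual societal cost
#'
#' Annualizes each participant's 4-week resource use under the arm's
#' [annualization_policy()] and values it at the unit prices and
#' education-matched wages. Expects columns `arm`, `education`,
#' `pfmt_hours_4wk`, `laundry_hours_4wk`, `aids_4wk`, `laundry_loads_4wk`.
#'
#' @param data Participant-level data frame (one row per participant).
#' @param prices A [price_config()].
#' @param policies Named list of policies per arm, as [default_policies()].
#' @return The input as a tibble with annualized amounts
#'   (`pfmt_hours_yr`, `laundry_hours_yr`, `aids_yr`, `laundry_loads_yr`),
#'   the six component cost columns and `total` appended.
#' @export
total_annual_cost <- function(data, prices = price_config(),
                              policies = default_policies()) {
  need <- c("arm", "education", "pfmt_hours_4wk", "laundry_hours_4wk",
            "aids_4wk", "laundry_loads_4wk")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing resource-use column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_arm <- setdiff(unique(data$arm), names(policies))
  if (length(bad_arm) > 0) {
    abort(paste0("no annualization policy for arm: ",
                 paste(bad_arm, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  blend <- unname(purrr::map_dbl(policies, annualization_blend)[out$arm])
  wpy <- unname(purrr::map_dbl(policies, "weeks_per_year")[out$arm])
  out$pfmt_hours_yr <- out$pfmt_hours_4wk * wpy / 4 * blend
  out$laundry_hours_yr <- annualize_constant(out$laundry_hours_4wk)
  out$aids_yr <- annualize_constant(out$aids_4wk)
  out$laundry_loads_yr <- annualize_constant(out$laundry_loads_4wk)
  out$assessment <- rep(prices$assessment_cost, nrow(out))
  out$treatment_delivery <- rep(0, nrow(out))
  out$pfmt_time <- time_cost(out$pfmt_hours_yr, out$education, prices)
  out$laundry_time <- time_cost(out$laundry_hours_yr, out$education, prices)
  out$aids_cost <- goods_cost(out$aids_yr, prices$aid_unit_price)
  out$laundry_loads_cost <- goods_cost(out$laundry_loads_yr, prices$laundry_load_price)
  out$total <- out$assessment + out$treatment_delivery + out$pfmt_time +
    out$laundry_time + out$aids_cost + out$laundry_loads_cost
  out
}

#' Arm-mean cost breakdowns
#'
#' Averages per-participant component costs within each arm (the
#' deterministic analysis operates on arithmetic group means).
#'
#' @param data Output of [total_annual_cost()].
#' @return Tibble with one row per arm: `arm`, mean annual amounts, and a
#'   mean [cost_breakdown()] in the component columns plus `total`.
#' @export
arm_cost_summary <- function(data) {
  need <- c("arm", "assessment", "treatment_delivery", "pfmt_time",
            "laundry_time", "aids_cost", "laundry_loads_cost")
  if (!all(need %in% names(data))) {
    abort("data must come from total_annual_cost()")
  }
  data |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::any_of(c(
        "pfmt_hours_yr", "laundry_hours_yr", "aids_yr", "laundry_loads_yr",
        "assessment", "treatment_delivery", "pfmt_time", "laundry_time",
        "aids_cost", "laundry_loads_cost", "total")), ~ mean(.x)),
      .groups = "drop"
    )
}

#' Turn an arm-mean cost row into a cost breakdown
#' @param summary_row One row of [arm_cost_summary()].
#' @return A one-row `cost_breakdown`.
#' @export
as_cost_breakdown <- function(summary_row) {
  cost_breakdown(
    assessment = summary_row$assessment,
    treatment_delivery = summary_row$treatment_delivery,
    pfmt_time = summary_row$pfmt_time,
    laundry_time = summary_row$laundry_time,
    aids = summary_row$aids_cost,
    laundry_loads = summary_row$laundry_loads_cost
  )
}
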