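#' Deterministic sensitivity scenario
#'
#' An ordered list of modifications to a [cost_breakdown()]: scale a
#' component by a factor, or exclude it (set to zero). QALYs are never
#' touched — the sensitivity analysis here is cost-side only.
#'
#' @param name Scenario label.
#' @param modifications Data frame with columns `component` (a
#'   [cost_breakdown()] field), `action` (`"scale"` or `"exclude"`) and
#'   `factor` (multiplier, used only for `scale`; must be > 0).
#' @return Object of class `cua_scenario`.
#' @export
scenario <- function(name, modifications) {
  mods <- tibble::as_tibble(modifications)
  if (!all(c("component", "action") %in% names(mods))) {
    abort("modifications need 'component' and 'action' columns")
  }
  if (!"factor" %in% names(mods)) mods$factor <- NA_real_
  bad <- setdiff(mods$component, cost_components())
  if (length(bad) > 0) {
    abort(paste0("unknown cost component(s): ", paste(bad, collapse = ", ")))
  }
  if (!all(mods$action %in% c("scale", "exclude"))) {
    abort("action must be 'scale' or 'exclude'")
  }
  scales <- mods$action == "scale"
  if (any(scales & (is.na(mods$factor) | mods$factor <= 0))) {
    abort("scale modifications need a positive factor")
  }
  mods$factor[!scales] <- NA_real_ # exclude ignores any factor
  structure(list(name = name, modifications = mods), class = "cua_scenario")
}

#' @export
print.cua_scenario <- function(x, ...) {
  cat("<scenario>", x$name, "\n")
  for (i in seq_len(nrow(x$modifications))) {
    m <- x$modifications[i, ]
    if (m$action == "scale") {
      cat(sprintf("  %s x %g\n", m$component, m$factor))
    } else {
      cat(sprintf("  %s excluded\n", m$component))
    }
  }
  invisible(x)
}

#' The analysis's four standard sensitivity scenarios
#'
#' Three one-way scenarios — participant's PFMT time halved, laundry cost
#' (the per-load goods cost) halved, participant's laundry time excluded —
#' and the multiway scenario combining all three. They probe the softest
#' assumptions of the societal costing: training can be done while doing
#' other things, and leakage laundry can be washed with other garments.
#'
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function() {
  list(
    pfmt_time_halved = scenario(
      "One-way: participant's time for PFMT halved",
      tibble::tibble(component = "pfmt_time", action = "scale", factor = 0.5)),
    laundry_cost_halved = scenario(
      "One-way: cost for laundry halved",
      tibble::tibble(component = "laundry_loads", action = "scale", factor = 0.5)),
    laundry_time_excluded = scenario(
      "One-way: participant's time for laundry not included",
      tibble::tibble(component = "laundry_time", action = "exclude",
                     factor = NA_real_)),
    multiway = scenario(
      "Multiway: PFMT time and laundry cost halved, laundry time excluded",
      tibble::tibble(component = c("pfmt_time", "laundry_loads", "laundry_time"),
                     action = c("scale", "scale", "exclude"),
                     factor = c(0.5, 0.5, NA_real_)))
  )
}

#' Read sensitivity scenarios from YAML or JSON
#'
#' Schema: a list of `{name, modifications: [{component, action, factor}]}`.
#'
#' @param path File path.
#' @return Named list of [scenario()] objects (named by a slug of `name`
#'   unless an `id` key is given).
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(sc) {
    mods <- dplyr::bind_rows(lapply(sc$modifications, function(m) {
      tibble::tibble(component = m$component, action = m$action,
                     factor = as.numeric(m$factor %||% NA_real_))
    }))
    scenario(sc$name, mods)
  })
  names(out) <- vapply(raw, function(sc) {
    sc$id %||% gsub("[^a-z0-9]+", "_", tolower(sc$name))
  }, character(1))
  out
}

#' Apply a scenario to a cost breakdown
#'
#' Scales or zeroes the named components and recomputes the total; untouched
#' components are returned bit-identical.
#'
#' @param breakdown A [cost_breakdown()].
#' @param scenario A [scenario()].
#' @return The modified `cost_breakdown`.
#' @export
apply_scenario <- function(breakdown, scenario) {
  stopifnot(inherits(breakdown, "cost_breakdown"),
            inherits(scenario, "cua_scenario"))
  out <- breakdown
  for (i in seq_len(nrow(scenario$modifications))) {
    m <- scenario$modifications[i, ]
    out[[m$component]] <- if (m$action == "exclude") {
      0 * out[[m$component]]
    } else {
      out[[m$component]] * m$factor
    }
  }
  out$total <- rowSums(out[cost_components()])
  out
}

#' Run the deterministic sensitivity analysis
#'
#' Applies each scenario identically to both arms' cost breakdowns, keeps
#' the QALY gains fixed, and recomputes the incremental result per row. The
#' base case is included as the first row.
#'
#' @param app,control One-row [cost_breakdown()]s of arm-mean costs.
#' @param qaly_app,qaly_control Mean QALY gains per arm.
#' @param scenarios Named list of [scenario()]s (default
#'   [default_scenarios()]).
#' @param include_base Prepend the unmodified base case (default TRUE).
#' @return Tibble of class `sensitivity_table`: one row per scenario with
#'   per-arm totals and QALY gains, `delta_cost`, `delta_qaly`, `icer`,
#'   `quadrant` and `dominance`.
#' @export
run_sensitivity <- function(app, control, qaly_app, qaly_control,
                            scenarios = default_scenarios(),
                            include_base = TRUE) {
  stopifnot(inherits(app, "cost_breakdown"), inherits(control, "cost_breakdown"),
            nrow(app) == 1, nrow(control) == 1)
  if (length(scenarios) == 0 && !include_base) {
    abort("at least one scenario (or the base case) is required")
  }
  cases <- list()
  if (include_base) {
    cases$base <- list(label = "Base case", app = app, control = control)
  }
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    cases[[nm]] <- list(label = sc$name,
                        app = apply_scenario(app, sc),
                        control = apply_scenario(control, sc))
  }
  rows <- purrr::imap(cases, function(cs, nm) {
    inc <- incremental(group_summary("app", cs$app$total, qaly_app),
                       group_summary("control", cs$control$total, qaly_control))
    tibble::tibble(
      scenario = nm, label = cs$label,
      app_total = cs$app$total, control_total = cs$control$total,
      app_qaly_gain = qaly_app, control_qaly_gain = qaly_control,
      delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
      icer = inc$icer, quadrant = inc$quadrant %||% NA_character_,
      dominance = inc$dominance
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sensitivity_table", class(tibble::tibble()))
  out
}
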