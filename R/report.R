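#' Run the full cost-utility analysis
#'
#' Two input modes:
#'
#' * **Participant-level** (`participants` given): scores the
#'   questionnaires, maps each completer's responses to utility weights,
#'   builds per-participant utility trajectories and QALY gains, annualizes
#'   and values resource use, and averages per arm.
#' * **Group-mean** (`arm_breakdowns` and `qaly_gains` given): takes
#'   arm-mean cost breakdowns and arm-mean QALY gains directly — the mode
#'   that reproduces a published deterministic analysis from its printed
#'   arm-level inputs.
#'
#' Either way the arm summaries feed the incremental analysis and the
#' deterministic sensitivity scenarios.
#'
#' @param participants Participant tibble ([read_participants()] /
#'   [generate_trial()]`$participants`), or NULL for group-mean mode.
#' @param arm_breakdowns Named list (`app`, `control`) of one-row
#'   [cost_breakdown()]s; group-mean mode only.
#' @param qaly_gains Named vector `c(app = , control = )` of mean QALY
#'   gains; group-mean mode only.
#' @param utility_config A [utility_index_config()].
#' @param prices A [price_config()].
#' @param policies Per-arm [annualization_policy()] list.
#' @param scenarios Named list of [scenario()]s.
#' @param t_followup,horizon Trajectory geometry in years.
#' @param aids_timepoint Timepoint whose aid consumption enters the cost
#'   model (`"baseline"`, the costing convention, or `"month3"`).
#' @param wtp_threshold Willingness-to-pay threshold in euro/QALY used for
#'   the acceptability flag (default 11,200, the "low incremental cost"
#'   anchor of 100,000 SEK).
#' @return Object of class `cua_report`: list with `cost_table` (per-arm
#'   component costs), `qaly_table`, `trajectories` (per-arm mean utility
#'   points), `sensitivity_table`, `base` (the base-case
#'   [incremental()] result), `acceptable` and `meta`.
#' @export
run_cua <- function(participants = NULL, arm_breakdowns = NULL,
                    qaly_gains = NULL,
                    utility_config = default_utility_config(),
                    prices = price_config(),
                    policies = default_policies(),
                    scenarios = default_scenarios(),
                    t_followup = 0.25, horizon = 1,
                    aids_timepoint = c("baseline", "month3"),
                    wtp_threshold = 11200) {
  aids_timepoint <- match.arg(aids_timepoint)
  if (is.null(participants) == (is.null(arm_breakdowns) || is.null(qaly_gains))) {
    abort(paste0("supply either participant-level data, or arm_breakdowns ",
                 "plus qaly_gains (group-mean mode)"))
  }
  if (!is.null(participants)) {
    pp <- tibble::as_tibble(participants)
    scored <- pp |>
      score_uisf(na_action = "omit") |>
      score_lutsqol(na_action = "omit") |>
      utility_weight(config = utility_config, na_action = "omit")
    completer_ids <- scored |>
      dplyr::count(.data$arm, .data$participant_id) |>
      dplyr::filter(.data$n == 2)
    cc <- dplyr::semi_join(scored, completer_ids,
                           by = c("arm", "participant_id"))
    uw <- cc |>
      dplyr::select(dplyr::all_of(c("arm", "participant_id", "timepoint",
                                    "utility"))) |>
      tidyr::pivot_wider(names_from = "timepoint", values_from = "utility") |>
      dplyr::rename(u_baseline = "baseline", u_followup = "month3") |>
      dplyr::filter(!is.na(.data$u_baseline), !is.na(.data$u_followup)) |>
      compute_qalys(t_followup = t_followup, horizon = horizon)
    qaly_table <- uw |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_u_baseline = mean(.data$u_baseline),
                       mean_u_followup = mean(.data$u_followup),
                       mean_qaly_gain = mean(.data$qaly_gain),
                       mean_days_equivalent = mean(.data$days_equivalent),
                       .groups = "drop")
    # cost side: follow-up resource use (aids optionally from baseline)
    res <- cc |>
      dplyr::filter(.data$timepoint == "month3") |>
      dplyr::select(-dplyr::all_of("aids_4wk")) |>
      dplyr::left_join(
        cc |>
          dplyr::filter(.data$timepoint == aids_timepoint) |>
          dplyr::select(dplyr::all_of(c("participant_id", "aids_4wk"))),
        by = "participant_id")
    costs <- total_annual_cost(res, prices = prices, policies = policies)
    cost_table <- arm_cost_summary(costs)
    arm_breakdowns <- list(
      app = as_cost_breakdown(dplyr::filter(cost_table, .data$arm == "app")),
      control = as_cost_breakdown(dplyr::filter(cost_table, .data$arm == "control")))
    qaly_gains <- setNames(qaly_table$mean_qaly_gain, qaly_table$arm)
    traj <- qaly_table |>
      dplyr::rowwise() |>
      dplyr::mutate(points = list(build_trajectory(
        .data$mean_u_baseline, .data$mean_u_followup, t_followup, horizon))) |>
      dplyr::ungroup()
    trajectories <- traj |>
      dplyr::select(dplyr::all_of(c("arm", "points"))) |>
      tidyr::unnest("points")
  } else {
    for (a in c("app", "control")) {
      if (!inherits(arm_breakdowns[[a]], "cost_breakdown")) {
        abort("arm_breakdowns must be named cost_breakdown objects (app, control)")
      }
    }
    if (!all(c("app", "control") %in% names(qaly_gains))) {
      abort("qaly_gains must be named c(app = , control = )")
    }
    cost_table <- dplyr::bind_rows(
      app = arm_breakdowns$app, control = arm_breakdowns$control,
      .id = "arm")
    qaly_table <- tibble::tibble(
      arm = c("app", "control"),
      mean_qaly_gain = unname(qaly_gains[c("app", "control")]),
      mean_days_equivalent = .data$mean_qaly_gain * DAYS_PER_YEAR)
    trajectories <- NULL
  }
  sens <- run_sensitivity(arm_breakdowns$app, arm_breakdowns$control,
                          qaly_gains[["app"]], qaly_gains[["control"]],
                          scenarios = scenarios)
  base <- incremental(
    group_summary("app", arm_breakdowns$app$total, qaly_gains[["app"]]),
    group_summary("control", arm_breakdowns$control$total, qaly_gains[["control"]]))
  structure(
    list(cost_table = tibble::as_tibble(cost_table),
         qaly_table = qaly_table,
         trajectories = trajectories,
         sensitivity_table = sens,
         base = base,
         acceptable = judge_willingness_to_pay(base, wtp_threshold),
         meta = list(mode = if (is.null(participants)) "group_mean" else
                       "participant", t_followup = t_followup,
                     horizon = horizon, wtp_threshold = wtp_threshold,
                     aids_timepoint = aids_timepoint,
                     currency = prices$currency)),
    class = "cua_report"
  )
}

#' @export
print.cua_report <- function(x, ...) {
  cat(sprintf("<cua_report> (%s mode, %.2f-yr horizon)\n", x$meta$mode,
              x$meta$horizon))
  cat("\nPer-arm annual cost (EUR):\n")
  print(x$cost_table)
  cat("\nQALY gains:\n")
  print(x$qaly_table)
  cat("\nBase case: ")
  print(x$base)
  cat(sprintf("acceptable at %.0f EUR/QALY: %s\n", x$meta$wtp_threshold,
              x$acceptable))
  cat("\nSensitivity analysis:\n")
  print(dplyr::select(x$sensitivity_table, -dplyr::all_of("label")))
  invisible(x)
}

#' @method tidy cua_report
#' @export
tidy.cua_report <- function(x, ...) x$sensitivity_table

#' @method glance cua_report
#' @export
glance.cua_report <- function(x, ...) {
  tibble::tibble(
    app_total_cost = x$cost_table$total[x$cost_table$arm == "app"],
    control_total_cost = x$cost_table$total[x$cost_table$arm == "control"],
    delta_cost = x$base$delta_cost, delta_qaly = x$base$delta_qaly,
    icer = x$base$icer, quadrant = x$base$quadrant %||% NA_character_,
    icer_min = min(x$sensitivity_table$icer, na.rm = TRUE),
    icer_max = max(x$sensitivity_table$icer, na.rm = TRUE),
    acceptable = x$acceptable
  )
}

#' Serialize / restore a CUA report
#'
#' `write_cua_report()` writes the report tables as CSV plus a single
#' machine-readable JSON (`report.json`, full double precision);
#' `read_cua_report()` rebuilds the tables from that JSON so a round trip
#' reproduces them exactly.
#'
#' @param report A [run_cua()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cua_report()`: the JSON path, invisibly;
#'   `read_cua_report()`: a list of the report's tables and scalars.
#' @export
write_cua_report <- function(report, dir) {
  stopifnot(inherits(report, "cua_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$cost_table, file.path(dir, "cost_table.csv"))
  readr::write_csv(report$qaly_table, file.path(dir, "qaly_table.csv"))
  readr::write_csv(report$sensitivity_table,
                   file.path(dir, "sensitivity_table.csv"))
  if (!is.null(report$trajectories)) {
    readr::write_csv(report$trajectories, file.path(dir, "trajectories.csv"))
  }
  payload <- list(
    cost_table = report$cost_table,
    qaly_table = report$qaly_table,
    trajectories = report$trajectories,
    sensitivity_table = report$sensitivity_table,
    base = tidy(report$base),
    acceptable = report$acceptable,
    meta = report$meta
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_cua_report
#' @param path Path to a `report.json`.
#' @export
read_cua_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    cost_table = tibble::as_tibble(raw$cost_table),
    qaly_table = tibble::as_tibble(raw$qaly_table),
    trajectories = if (!is.null(raw$trajectories))
      tibble::as_tibble(raw$trajectories) else NULL,
    sensitivity_table = tibble::as_tibble(raw$sensitivity_table),
    base = tibble::as_tibble(raw$base),
    acceptable = raw$acceptable,
    meta = raw$meta
  )
  out
}
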