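participant_columns <- function() {
  c("participant_id", "arm", "education", "timepoint", lutsqol_items(),
    "uisf_freq", "uisf_amount", "uisf_impact",
    "pfmt_hours_4wk", "laundry_hours_4wk", "aids_4wk", "laundry_loads_4wk")
}

#' Write a participant table to CSV
#'
#' One row per participant x timepoint with the documented header; the
#' generator seed is recorded in a leading `#` comment line, which
#' [read_participants()] skips.
#'
#' @param trial A [generate_trial()] result or a participant tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_participants <- function(trial, path) {
  pp <- if (inherits(trial, "synthetic_trial")) trial$participants else
    tibble::as_tibble(trial)
  seed <- if (inherits(trial, "synthetic_trial")) trial$config$seed else NA
  header <- if (is.na(seed)) "# participant records" else
    sprintf("# synthetic trial, generator seed %d", seed)
  writeLines(header, path)
  readr::write_csv(pp[intersect(participant_columns(), names(pp))], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate a participant CSV
#'
#' Validates every row: known arm and timepoint labels, item levels in 1-4
#' (missing allowed, for completer analyses), UI SF items within their
#' maxima, non-negative resource use. All problems are collected and
#' reported together with their row number and column before aborting.
#'
#' @param path CSV file with the columns of [write_participants()]; lines
#'   starting with `#` are ignored.
#' @return Validated participant tibble.
#' @export
read_participants <- function(path) {
  pp <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          arm = readr::col_character(),
                          education = readr::col_character(),
                          timepoint = readr::col_character(),
                          .default = readr::col_double()))
  missing_cols <- setdiff(participant_columns(), names(pp))
  if (length(missing_cols) > 0) {
    abort(paste0("participant file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  flag <- function(rows, col, why) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("row %d, column %s: %s", rows, col, why))
    }
  }
  flag(which(!pp$arm %in% c("app", "control")), "arm", "unknown arm label")
  flag(which(!pp$timepoint %in% c("baseline", "month3")), "timepoint",
       "unknown timepoint")
  for (it in lutsqol_items()) {
    flag(which(!is.na(pp[[it]]) & !(pp[[it]] %in% 1:4)), it,
         "item level outside 1-4")
  }
  maxima <- c(uisf_freq = 5, uisf_amount = 6, uisf_impact = 10)
  for (col in names(maxima)) {
    x <- pp[[col]]
    flag(which(!is.na(x) & (x < 0 | x > maxima[[col]] | x != round(x))), col,
         sprintf("outside [0, %d]", maxima[[col]]))
  }
  for (col in c("pfmt_hours_4wk", "laundry_hours_4wk", "aids_4wk",
                "laundry_loads_4wk")) {
    flag(which(!is.na(pp[[col]]) & pp[[col]] < 0), col, "negative quantity")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid participant record(s):\n  ",
                 paste(head(problems, 20), collapse = "\n  "),
                 if (length(problems) > 20)
                   sprintf("\n  ... and %d more", length(problems) - 20) else ""))
  }
  pp
}

#' Read arm-level group-mean inputs
#'
#' Loads the YAML of arm-mean annual amounts, arm-mean component costs and
#' arm-mean QALY gains used by the group-mean analysis mode (see the
#' bundled `extdata/arm_inputs.yaml`).
#'
#' @param path YAML file with keys `amounts_annual`, `component_costs`,
#'   `qaly_gains`, each keyed by arm.
#' @return List with `amounts_annual` (named list of numeric vectors),
#'   `breakdowns` (named list of [cost_breakdown()]s built from the
#'   component costs) and `qaly_gains` (named numeric vector).
#' @export
read_arm_inputs <- function(path) {
  raw <- yaml::read_yaml(path)
  breakdowns <- lapply(raw$component_costs, function(cc) {
    cost_breakdown(
      assessment = cc$assessment,
      treatment_delivery = cc$treatment_delivery %||% 0,
      pfmt_time = cc$pfmt_time, laundry_time = cc$laundry_time,
      aids = cc$aids, laundry_loads = cc$laundry_loads)
  })
  list(
    amounts_annual = lapply(raw$amounts_annual, function(a) unlist(a)),
    breakdowns = breakdowns,
    qaly_gains = unlist(raw$qaly_gains)
  )
}
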