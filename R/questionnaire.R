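#' ICIQ-LUTSqol item column names
#'
#' The condition-specific quality-of-life questionnaire has 19 items, each
#' answered on a 4-point scale (1 = not at all / never, 4 = a lot / all the
#' time). Participant tables carry them as columns `item01` ... `item19`.
#'
#' @return Character vector of the 19 item column names.
#' @export
lutsqol_items <- function() sprintf("item%02d", 1:19)

# Validate a matrix/data frame of item levels; returns the numeric matrix.
# Errors name the offending item (and row where known).
check_item_levels <- function(data, items, na_action = c("error", "omit"),
                              levels = 1:4, what = "ICIQ-LUTSqol") {
  na_action <- match.arg(na_action)
  missing_cols <- setdiff(items, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " item column(s) missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(data)[items])
  storage.mode(m) <- "double"
  for (it in items) {
    x <- m[, it]
    if (anyNA(x) && na_action == "error") {
      abort(paste0(what, " item ", it, " has missing answers (row ",
                   paste(which(is.na(x)), collapse = ", "), ")"))
    }
    bad <- which(!is.na(x) & (!(x %in% levels)))
    if (length(bad) > 0) {
      abort(paste0(what, " item ", it, " outside allowed levels {",
                   paste(levels, collapse = ","), "} in row ",
                   paste(bad, collapse = ", ")))
    }
  }
  m
}

#' Score the ICIQ-LUTSqol questionnaire
#'
#' Sums the 19 item levels into the overall impact score, which ranges from
#' 19 (no impact on quality of life) to 76 (maximal impact).
#'
#' @param data Data frame with one row per participant x timepoint and the
#'   item columns [lutsqol_items()].
#' @param na_action `"error"` (default) fails naming the item with missing
#'   answers; `"omit"` scores those rows as `NA` so a completer analysis can
#'   drop them downstream.
#' @return The input as a tibble with a `lutsqol_total` column appended.
#' @examples
#' resp <- tibble::as_tibble(as.list(setNames(rep(1, 19), lutsqol_items())))
#' score_lutsqol(resp)$lutsqol_total # 19, the floor of the scale
#' @export
score_lutsqol <- function(data, na_action = c("error", "omit")) {
  m <- check_item_levels(data, lutsqol_items(), na_action)
  out <- tibble::as_tibble(data)
  out$lutsqol_total <- as.numeric(rowSums(m))
  out
}

#' Score the ICIQ-UI SF questionnaire
#'
#' Sums the three short-form items (leakage frequency, leakage amount, and
#' overall interference with everyday life) into a severity score from 0 to
#' 21; higher scores mean greater severity.
#'
#' @param data Data frame with columns `uisf_freq`, `uisf_amount`,
#'   `uisf_impact`.
#' @param maxima Named per-item maxima. The instrument scores frequency 0-5,
#'   amount 0-6 and interference 0-10; configurable because only the 0-21
#'   total is fixed by convention.
#' @inheritParams score_lutsqol
#' @return The input as a tibble with a `uisf_total` column appended.
#' @export
score_uisf <- function(data, maxima = c(uisf_freq = 5, uisf_amount = 6, uisf_impact = 10),
                       na_action = c("error", "omit")) {
  stopifnot(all(c("uisf_freq", "uisf_amount", "uisf_impact") %in% names(maxima)))
  na_action <- match.arg(na_action)
  cols <- names(maxima)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("ICIQ-UI SF column(s) missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(data)[cols])
  storage.mode(m) <- "double"
  for (it in cols) {
    x <- m[, it]
    if (anyNA(x) && na_action == "error") {
      abort(paste0("ICIQ-UI SF item ", it, " has missing answers"))
    }
    bad <- which(!is.na(x) & (x < 0 | x > maxima[[it]] | x != round(x)))
    if (length(bad) > 0) {
      abort(paste0("ICIQ-UI SF item ", it, " outside [0, ", maxima[[it]],
                   "] in row ", paste(bad, collapse = ", ")))
    }
  }
  out <- tibble::as_tibble(data)
  out$uisf_total <- as.numeric(rowSums(m))
  out
}

#' Severity band of an ICIQ-UI SF total score
#'
#' Maps the 0-21 total to the conventional severity categories: 1-5 slight,
#' 6-12 moderate, 13-18 severe, 19-21 very severe. A total of 0 (no leakage
#' reported) falls below the published bands and is labelled `"none"`.
#'
#' @param total Numeric vector of total scores in `[0, 21]`.
#' @return Ordered factor with levels none < slight < moderate < severe <
#'   very severe.
#' @examples
#' severity_band(c(0, 3, 11, 15, 19))
#' @export
severity_band <- function(total) {
  if (any(!is.na(total) & (total < 0 | total > 21))) {
    abort("ICIQ-UI SF total outside [0, 21]")
  }
  labs <- c("none", "slight", "moderate", "severe", "very severe")
  cut(total, breaks = c(-Inf, 0, 5, 12, 18, 21), labels = labs,
      ordered_result = TRUE)
}

#' @describeIn severity_band Data-frame verb: appends a `severity` column
#'   derived from `total_col`.
#' @param data Data frame holding the total-score column.
#' @param total_col Name of the column with the total score.
#' @export
categorize_severity <- function(data, total_col = "uisf_total") {
  if (!total_col %in% names(data)) {
    abort(paste0("column '", total_col, "' not found"))
  }
  out <- tibble::as_tibble(data)
  out$severity <- severity_band(out[[total_col]])
  out
}
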