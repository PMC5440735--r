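#' Preference-based utility index configuration
#'
#' A condition-specific preference-based index reduces 9 of the 19
#' ICIQ-LUTSqol items to a "health state" and maps that state to a utility
#' weight anchored at 0 (worst imaginable health) and 1 (best imaginable
#' health). The mapping used here is the standard additive-decrement form:
#'
#' \deqn{u = \max(\mathrm{floor},\; b - \sum_{i=1}^{9} d_i(\ell_i))}
#'
#' where \eqn{b} is the base value for the best state, \eqn{\ell_i} the level
#' (1-4) of selected item \eqn{i}, and \eqn{d_i(1) = 0}. Decrements must be
#' non-decreasing in level so that worse answers never raise the utility.
#'
#' The published valuation coefficients for this index are not in the public
#' domain, so the package ships a clearly-flagged synthetic placeholder
#' ([default_utility_config()]); real coefficients can be supplied from a
#' YAML/JSON file via [read_utility_config()].
#'
#' @param selected_items Character vector of exactly 9 item column names.
#' @param base_value Utility of the best state (all selected items at level
#'   1); at most 1.
#' @param decrements Numeric matrix (9 x 4) of per-item, per-level utility
#'   decrements; rows named by `selected_items`, columns levels 1-4. Column 1
#'   must be all 0; entries non-negative and non-decreasing along each row.
#' @param clamp_floor Minimum utility (>= 0) after subtraction.
#' @return An object of class `utility_index_config`.
#' @export
utility_index_config <- function(selected_items, base_value, decrements,
                                 clamp_floor = 0) {
  if (length(selected_items) != 9) {
    abort("a health-state classification selects exactly 9 items")
  }
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(9, 4))) {
    abort("decrements must be a 9 x 4 matrix (items x levels)")
  }
  rownames(decrements) <- selected_items
  colnames(decrements) <- paste0("level", 1:4)
  if (any(decrements < 0)) abort("utility decrements must be non-negative")
  if (any(decrements[, 1] != 0)) abort("level-1 decrements must be 0")
  if (any(apply(decrements, 1, function(d) any(diff(d) < 0)))) {
    abort("decrements must be non-decreasing in level")
  }
  if (base_value > 1) abort("base_value must be <= 1")
  if (clamp_floor < 0) abort("clamp_floor must be >= 0")
  if (clamp_floor > base_value) abort("clamp_floor exceeds base_value")
  structure(
    list(selected_items = selected_items, base_value = base_value,
         decrements = decrements, clamp_floor = clamp_floor),
    class = "utility_index_config"
  )
}

#' Placeholder utility index
#'
#' A synthetic stand-in for the (unavailable) published valuation algorithm:
#' items 3-11, base value 0.99, identical per-level decrements
#' (0, 0.005, 0.011, 0.018) for every item, floor 0. The decrement scale is
#' chosen so a clinically relevant LUTSqol improvement (a few points) maps to
#' a utility gain of order 0.01 per year, the magnitude typical of
#' conservative incontinence treatment. Absolute utility levels from this
#' placeholder carry no external meaning; replace it with real coefficients
#' for substantive work.
#'
#' @return A `utility_index_config`.
#' @export
default_utility_config <- function() {
  items <- lutsqol_items()[3:11]
  dec <- matrix(rep(c(0, 0.005, 0.011, 0.018), each = 9), nrow = 9,
                dimnames = list(items, paste0("level", 1:4)))
  cfg <- utility_index_config(items, base_value = 0.99, decrements = dec,
                              clamp_floor = 0)
  attr(cfg, "placeholder") <- TRUE
  cfg
}

#' @export
print.utility_index_config <- function(x, ...) {
  cat("<utility_index_config>\n")
  cat("  items:", paste(x$selected_items, collapse = ", "), "\n")
  cat(sprintf("  base %.3f, floor %.3f\n", x$base_value, x$clamp_floor))
  if (isTRUE(attr(x, "placeholder"))) {
    cat("  [synthetic placeholder coefficients - not a published valuation]\n")
  }
  invisible(x)
}

#' Read a utility index configuration from YAML or JSON
#'
#' Expected keys: `selected_items`, `base_value`, `clamp_floor`, and
#' `decrements` as a mapping item -> list of 4 numbers (levels 1-4).
#'
#' @param path File path.
#' @return A `utility_index_config`.
#' @export
read_utility_config <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- as.character(raw$selected_items)
  dec <- do.call(rbind, lapply(items, function(it) {
    d <- raw$decrements[[it]]
    if (is.null(d)) abort(paste0("no decrements for selected item ", it))
    as.numeric(d)
  }))
  utility_index_config(items, base_value = as.numeric(raw$base_value),
                       decrements = dec,
                       clamp_floor = as.numeric(raw$clamp_floor %||% 0))
}

#' Project responses onto the health-state classification
#'
#' Extracts, in configuration order, the levels of the 9 items that make up
#' the health state.
#'
#' @param data Data frame of responses with the LUTSqol item columns.
#' @param config A [utility_index_config()].
#' @inheritParams score_lutsqol
#' @return Tibble with the 9 selected item columns (one row per response),
#'   in configuration order.
#' @export
classify_health_state <- function(data, config = default_utility_config(),
                                  na_action = c("error", "omit")) {
  m <- check_item_levels(data, config$selected_items, na_action)
  tibble::as_tibble(as.data.frame(m))
}

#' Utility weight of a single health state
#'
#' @param levels Integer vector of 9 item levels (1-4), in the order of
#'   `config$selected_items`.
#' @param config A [utility_index_config()].
#' @return Utility in `[0, 1]`.
#' @export
utility_from_levels <- function(levels, config = default_utility_config()) {
  if (length(levels) != length(config$selected_items)) {
    abort("state length must match the number of selected items")
  }
  if (anyNA(levels)) return(NA_real_)
  if (any(!(levels %in% 1:4))) abort("health-state levels must be in 1..4")
  dec <- sum(config$decrements[cbind(seq_along(levels), levels)])
  max(config$clamp_floor, config$base_value - dec)
}

#' Attach utility weights to scored responses
#'
#' Classifies each row's health state and applies the additive-decrement
#' algorithm of `config`.
#'
#' @inheritParams classify_health_state
#' @return The input as a tibble with a `utility` column appended (values in
#'   `[0, 1]`; `NA` where items were missing and `na_action = "omit"`).
#' @export
utility_weight <- function(data, config = default_utility_config(),
                           na_action = c("error", "omit")) {
  m <- check_item_levels(data, config$selected_items, na_action)
  u <- apply(m, 1, function(lv) {
    if (anyNA(lv)) return(NA_real_)
    max(config$clamp_floor,
        config$base_value - sum(config$decrements[cbind(seq_along(lv), lv)]))
  })
  out <- tibble::as_tibble(data)
  out$utility <- as.numeric(u)
  out
}
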