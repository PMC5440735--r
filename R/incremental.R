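#' Arm-level summary for the incremental analysis
#'
#' The (mean annual cost, mean annual QALY gain) pair for one arm — the two
#' numbers that enter the incremental cost-effectiveness ratio.
#'
#' @param arm Arm label.
#' @param mean_cost Mean annual societal cost per participant (euro).
#' @param mean_qaly_gain Mean QALY gain per participant over the horizon.
#' @return One-row tibble of class `group_summary`.
#' @export
group_summary <- function(arm, mean_cost, mean_qaly_gain) {
  if (mean_cost < 0) abort("mean_cost must be non-negative")
  if (abs(mean_qaly_gain) > 1) abort("|mean_qaly_gain| cannot exceed 1 over a 1-year horizon")
  out <- tibble::tibble(arm = arm, mean_cost = as.numeric(mean_cost),
                        mean_qaly_gain = as.numeric(mean_qaly_gain))
  class(out) <- c("group_summary", class(tibble::tibble()))
  out
}

# sign pair -> cost-effectiveness plane quadrant
ce_quadrant <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 || delta_qaly == 0) return(NA_character_)
  if (delta_cost > 0 && delta_qaly > 0) "NE"
  else if (delta_cost < 0 && delta_qaly > 0) "SE"
  else if (delta_cost > 0 && delta_qaly < 0) "NW"
  else "SW"
}

#' Incremental cost-effectiveness of one arm over another
#'
#' Computes \eqn{\Delta C = C_{int} - C_{comp}}, \eqn{\Delta Q}, and the
#' ICER \eqn{\Delta C / \Delta Q}, and places the comparison on the
#' cost-effectiveness plane: NE (more costly, more effective), SE (cheaper,
#' more effective — dominant), NW (more costly, less effective — dominated),
#' SW (cheaper, less effective). When \eqn{\Delta Q = 0} the ICER is
#' undefined and reported as `NA`, not as an infinity. A negative ICER is
#' ambiguous on its own, so dominance is always carried alongside the ratio.
#'
#' @param intervention,comparator [group_summary()] rows.
#' @return Object of class `incremental_result` with fields `delta_cost`,
#'   `delta_qaly`, `icer`, `icer_defined`, `quadrant`, `dominance`, `note`.
#' @examples
#' app <- group_summary("app", 547.0, 0.01006)
#' ctl <- group_summary("control", 482.4, 0.00158)
#' incremental(app, ctl)
#' @export
incremental <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "group_summary"),
            inherits(comparator, "group_summary"))
  dc <- intervention$mean_cost - comparator$mean_cost
  dq <- intervention$mean_qaly_gain - comparator$mean_qaly_gain
  quadrant <- ce_quadrant(dc, dq)
  icer <- if (dq != 0) dc / dq else NA_real_
  dominance <- if (is.na(quadrant)) "none" else
    switch(quadrant, SE = "dominant", NW = "dominated", "none")
  note <- if (dq == 0) {
    "delta QALY is zero: ICER undefined"
  } else if (!is.na(icer) && icer < 0) {
    paste0("negative ICER: interpret via quadrant (", quadrant, ", ",
           dominance, ")")
  } else {
    NA_character_
  }
  structure(
    list(intervention = intervention$arm, comparator = comparator$arm,
         delta_cost = dc, delta_qaly = dq, icer = icer,
         icer_defined = dq != 0, quadrant = quadrant, dominance = dominance,
         note = note),
    class = "incremental_result"
  )
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.1f EUR, dQALY %.5f\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("ICER %.1f EUR/QALY  [%s%s]\n", x$icer,
                x$quadrant %||% "on-axis",
                if (x$dominance != "none") paste0(", ", x$dominance) else ""))
  } else {
    cat("ICER undefined (dQALY = 0)\n")
  }
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @method tidy incremental_result
#' @export
tidy.incremental_result <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention, comparator = x$comparator,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, quadrant = x$quadrant %||% NA_character_,
    dominance = x$dominance
  )
}

#' Acceptability at a willingness-to-pay threshold
#'
#' NE results are acceptable when the ICER does not exceed the threshold;
#' SE (dominant) results are always acceptable; NW (dominated) never. SW
#' results — cheaper but less effective — are judged by the symmetric rule:
#' acceptable when the saving per QALY forgone is at least the threshold
#' (i.e. the SW ICER, which is positive, is at least the threshold).
#'
#' @param result An [incremental()] result.
#' @param threshold Willingness to pay in euro per QALY (> 0). The Swedish
#'   convention treats incremental costs up to about 11,200 EUR/QALY
#'   (100,000 SEK) as low.
#' @return Logical: acceptable at this threshold. `NA` when both deltas are
#'   zero (indifferent).
#' @export
judge_willingness_to_pay <- function(result, threshold = 11200) {
  stopifnot(inherits(result, "incremental_result"))
  if (threshold <= 0) abort("threshold must be positive")
  if (is.na(result$quadrant)) {
    # on an axis: pure saving is acceptable, pure extra cost is not,
    # no difference at all is indifferent
    if (result$delta_qaly == 0 && result$delta_cost == 0) return(NA)
    if (result$delta_qaly == 0) return(result$delta_cost < 0)
    return(result$delta_qaly > 0) # same cost, QALY difference decides
  }
  switch(result$quadrant,
         SE = TRUE,
         NW = FALSE,
         NE = result$icer <= threshold,
         SW = result$icer >= threshold)
}
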