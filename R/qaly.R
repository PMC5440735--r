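#' Utility trajectory over the analysis horizon
#'
#' A piecewise-linear utility curve: assessment times in years (starting at
#' 0) with matching utility weights in `[0, 1]`. If the last assessment falls
#' before the horizon, the final utility is carried forward unchanged
#' (constant extrapolation), matching the assumption that the follow-up
#' utility remains stable for the remainder of the year.
#'
#' @param times Strictly increasing assessment times in years; first must
#'   be 0, last at most `horizon`.
#' @param utilities Utility weights matching `times`.
#' @param horizon Analysis horizon in years (default 1).
#' @return A tibble of class `utility_trajectory` with columns `time` and
#'   `utility`; the horizon is carried as an attribute.
#' @export
utility_trajectory <- function(times, utilities, horizon = 1) {
  if (length(times) != length(utilities) || length(times) < 1) {
    abort("times and utilities must be non-empty and of equal length")
  }
  if (times[1] != 0) abort("trajectory must start at time 0")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (horizon <= 0) abort("horizon must be positive")
  if (tail(times, 1) > horizon) abort("assessment times must not exceed the horizon")
  if (any(utilities < 0 | utilities > 1)) abort("utilities must lie in [0, 1]")
  structure(
    tibble::tibble(time = as.numeric(times), utility = as.numeric(utilities)),
    horizon = as.numeric(horizon),
    class = c("utility_trajectory", class(tibble::tibble()))
  )
}

#' Build the two-assessment trajectory used in the 1-year analysis
#'
#' Utility changes linearly from baseline to the follow-up assessment and is
#' then held constant to the horizon.
#'
#' @param u_baseline,u_followup Utility weights at baseline and follow-up.
#' @param t_followup Follow-up time in years (default 0.25, i.e. 3 months).
#' @param horizon Analysis horizon in years (default 1).
#' @return A [utility_trajectory()] with points `(0, u_baseline)`,
#'   `(t_followup, u_followup)` and, when `t_followup < horizon`,
#'   `(horizon, u_followup)`.
#' @examples
#' build_trajectory(0.90, 0.94, t_followup = 0.25, horizon = 1)
#' @export
build_trajectory <- function(u_baseline, u_followup, t_followup = 0.25,
                             horizon = 1) {
  if (t_followup <= 0 || t_followup > horizon) {
    abort("t_followup must lie in (0, horizon]")
  }
  if (t_followup < horizon) {
    utility_trajectory(c(0, t_followup, horizon),
                       c(u_baseline, u_followup, u_followup), horizon)
  } else {
    utility_trajectory(c(0, t_followup), c(u_baseline, u_followup), horizon)
  }
}

#' QALYs by area under the utility curve
#'
#' Integrates the piecewise-linear utility trajectory over `[0, horizon]`
#' with the trapezoidal rule (exact for a piecewise-linear curve), carrying
#' the last utility forward to the horizon when needed. The QALY gain is the
#' area between the trajectory and the baseline utility held constant over
#' the horizon — the quantity that captures treatment-attributable change.
#'
#' @param traj A [utility_trajectory()].
#' @return An object of class `qaly_result`: a list with `qaly_total`,
#'   `qaly_gain` (= total − baseline utility × horizon) and
#'   `days_equivalent` (= gain × 365.25).
#' @examples
#' qaly_auc(build_trajectory(0.90, 0.94))$qaly_gain # 0.035
#' @export
qaly_auc <- function(traj) {
  stopifnot(inherits(traj, "utility_trajectory"))
  h <- attr(traj, "horizon")
  t <- traj$time
  u <- traj$utility
  if (tail(t, 1) < h) { # constant extrapolation to the horizon
    t <- c(t, h)
    u <- c(u, tail(u, 1))
  }
  total <- sum(diff(t) * (head(u, -1) + tail(u, -1)) / 2)
  gain <- total - u[1] * h
  structure(
    list(qaly_total = total, qaly_gain = gain,
         days_equivalent = gain * DAYS_PER_YEAR, horizon = h),
    class = "qaly_result"
  )
}

#' @export
print.qaly_result <- function(x, ...) {
  cat(sprintf("QALYs over %.2f yr: %.5f (gain %.5f, %.1f days in full health)\n",
              x$horizon, x$qaly_total, x$qaly_gain, x$days_equivalent))
  invisible(x)
}

#' @method tidy qaly_result
#' @export
tidy.qaly_result <- function(x, ...) {
  tibble::tibble(qaly_total = x$qaly_total, qaly_gain = x$qaly_gain,
                 days_equivalent = x$days_equivalent, horizon = x$horizon)
}

#' Per-row QALY computation for a utility table
#'
#' Applies the two-assessment trajectory and AUC rule row by row; the closed
#' form for that shape is
#' \eqn{\mathrm{gain} = (u_1 - u_0)\,(h - t/2)}.
#'
#' @param data Data frame with baseline and follow-up utility columns.
#' @param baseline_col,followup_col Column names (defaults `u_baseline`,
#'   `u_followup`).
#' @inheritParams build_trajectory
#' @return The input as a tibble with `qaly_total`, `qaly_gain` and
#'   `days_equivalent` appended (`NA` rows propagate).
#' @export
compute_qalys <- function(data, baseline_col = "u_baseline",
                          followup_col = "u_followup", t_followup = 0.25,
                          horizon = 1) {
  if (!all(c(baseline_col, followup_col) %in% names(data))) {
    abort("baseline/follow-up utility columns not found")
  }
  if (t_followup <= 0 || t_followup > horizon) {
    abort("t_followup must lie in (0, horizon]")
  }
  u0 <- data[[baseline_col]]
  u1 <- data[[followup_col]]
  gain <- (u1 - u0) * (horizon - t_followup / 2)
  out <- tibble::as_tibble(data)
  out$qaly_total <- u0 * horizon + gain
  out$qaly_gain <- gain
  out$days_equivalent <- gain * DAYS_PER_YEAR
  out
}

#' Utility change implied by a QALY gain
#'
#' Inverts the two-assessment AUC geometry: for a trajectory that moves
#' linearly from `u0` to `u0 + delta` by `t_followup` and stays constant to
#' the horizon, the gain is `delta * (horizon - t_followup/2)`; this returns
#' `delta` for a given gain. Useful as a diagnostic and for constructing
#' trajectories that reproduce a published QALY gain.
#'
#' @param qaly_gain QALY gain over the horizon.
#' @inheritParams build_trajectory
#' @return The implied utility change at follow-up.
#' @examples
#' implied_utility_change(0.035) # 0.04
#' @export
implied_utility_change <- function(qaly_gain, t_followup = 0.25, horizon = 1) {
  if (t_followup <= 0 || t_followup > horizon) {
    abort("t_followup must lie in (0, horizon]")
  }
  denom <- horizon - t_followup / 2
  if (abs(denom) < .Machine$double.eps) {
    abort("degenerate trajectory geometry: horizon - t_followup/2 is zero")
  }
  qaly_gain / denom
}
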