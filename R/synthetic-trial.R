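#' Configuration for the synthetic two-arm trial
#'
#' Describes the trial the generator emulates: a randomized comparison of
#' app-delivered pelvic floor muscle training (app arm, n = 62) against no
#' treatment (control arm, n = 61) in community-dwelling women with stress
#' urinary incontinence, assessed at baseline and 3 months. Defaults encode
#' the study conditions: baseline ICIQ-LUTSqol 34.1 (SD 6.1) vs 34.8 (SD
#' 6.1), mean 3-month LUTSqol reductions 4.8 vs 0.7 (SDs derived from the
#' reported 95% CIs), baseline ICIQ-UI SF 11.1 (3.0) vs 11.0 (2.6), one
#' dropout per arm plus 3 app-arm participants with missing follow-up QoL,
#' 84% vs 75% with >= 3 years of university education, and 4-week resource
#' use consistent with the arm-mean annual amounts of the cost table
#' (e.g. annual PFMT 15.66 h vs 9.91 h, aids 114.40 vs 169.60).
#'
#' @param n_app,n_control Arm sizes.
#' @param dropout_per_arm Participants lost to follow-up per arm (no
#'   3-month record at all).
#' @param missing_qol_app App-arm completers whose 3-month LUTSqol items are
#'   missing (item-level missingness; resource use still observed).
#' @param baseline_lutsqol_mean,baseline_lutsqol_sd Named per-arm baseline
#'   LUTSqol total mean/SD.
#' @param lutsqol_reduction_mean,lutsqol_reduction_sd Named per-arm mean/SD
#'   of the baseline-to-3-month LUTSqol reduction (positive = improvement).
#' @param baseline_uisf_mean,baseline_uisf_sd Named per-arm baseline
#'   ICIQ-UI SF total mean/SD.
#' @param annual_amounts Named list (per arm) of target mean annual resource
#'   amounts `c(pfmt_hours, laundry_hours, aids, laundry_loads)`; converted
#'   to 4-week generator means by inverting the arm's annualization rule.
#' @param resource_cv Coefficient of variation of the gamma resource-use
#'   draws (default 0.8; the study reports no dispersions, so this is an
#'   assumption of right-skewed individual use).
#' @param education_fraction Named per-arm share with >= 3 years university.
#' @param policies Per-arm [annualization_policy()] list used for the
#'   annual-to-4-week inversion.
#' @param t_followup Follow-up time in years.
#' @param seed Integer RNG seed; the trial is fully reproducible from it.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_app = 62, n_control = 61,
                         dropout_per_arm = 1, missing_qol_app = 3,
                         baseline_lutsqol_mean = c(app = 34.1, control = 34.8),
                         baseline_lutsqol_sd = c(app = 6.1, control = 6.1),
                         lutsqol_reduction_mean = c(app = 4.8, control = 0.7),
                         lutsqol_reduction_sd = c(app = 5.4, control = 4.6),
                         baseline_uisf_mean = c(app = 11.1, control = 11.0),
                         baseline_uisf_sd = c(app = 3.0, control = 2.6),
                         annual_amounts = list(
                           app = c(pfmt_hours = 15.66, laundry_hours = 1.30,
                                   aids = 114.40, laundry_loads = 10.40),
                           control = c(pfmt_hours = 9.91, laundry_hours = 3.38,
                                       aids = 169.60, laundry_loads = 27.04)),
                         resource_cv = 0.8,
                         education_fraction = c(app = 0.84, control = 0.75),
                         policies = default_policies(),
                         t_followup = 0.25,
                         seed = 1L) {
  arms <- c("app", "control")
  for (x in list(baseline_lutsqol_mean, baseline_lutsqol_sd,
                 lutsqol_reduction_mean, lutsqol_reduction_sd,
                 baseline_uisf_mean, baseline_uisf_sd, education_fraction)) {
    if (!all(arms %in% names(x))) abort("per-arm parameters must be named app/control")
  }
  n <- c(app = n_app, control = n_control)
  if (any(n <= dropout_per_arm)) abort("arm sizes must exceed the dropout count")
  if (n_app - dropout_per_arm < missing_qol_app) {
    abort("more missing-QoL participants than app-arm completers")
  }
  if (any(baseline_lutsqol_mean < 19 | baseline_lutsqol_mean > 76)) {
    abort("baseline LUTSqol means must lie in [19, 76]")
  }
  if (any(baseline_uisf_mean < 0 | baseline_uisf_mean > 21)) {
    abort("baseline UI SF means must lie in [0, 21]")
  }
  if (any(c(baseline_lutsqol_sd, lutsqol_reduction_sd, baseline_uisf_sd) < 0) ||
      resource_cv < 0) {
    abort("dispersions must be non-negative")
  }
  if (any(education_fraction < 0 | education_fraction > 1)) {
    abort("education fractions must lie in [0, 1]")
  }
  if (any(unlist(annual_amounts) < 0)) abort("annual amounts must be non-negative")
  # invert the arm annualization to get 4-week generator means
  res4 <- lapply(arms, function(a) {
    ann <- annual_amounts[[a]]
    pol <- policies[[a]]
    fac <- pol$weeks_per_year / 4
    c(pfmt_hours = unname(ann[["pfmt_hours"]] / (fac * annualization_blend(pol))),
      laundry_hours = unname(ann[["laundry_hours"]] / fac),
      aids = unname(ann[["aids"]] / fac),
      laundry_loads = unname(ann[["laundry_loads"]] / fac))
  })
  names(res4) <- arms
  structure(
    list(n = n, dropout_per_arm = dropout_per_arm,
         missing_qol_app = missing_qol_app,
         baseline_lutsqol_mean = baseline_lutsqol_mean,
         baseline_lutsqol_sd = baseline_lutsqol_sd,
         lutsqol_reduction_mean = lutsqol_reduction_mean,
         lutsqol_reduction_sd = lutsqol_reduction_sd,
         baseline_uisf_mean = baseline_uisf_mean,
         baseline_uisf_sd = baseline_uisf_sd,
         annual_amounts = annual_amounts, resource_means_4wk = res4,
         resource_cv = resource_cv, education_fraction = education_fraction,
         policies = policies, t_followup = t_followup,
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

# Spread a LUTSqol total over the 19 items, monotone in the total.
# `order` is a per-participant permutation: items earlier in the order pick
# up extra points first, so profiles differ across participants but evolve
# gradually within one.
items_from_total <- function(total, order) {
  extra <- round(total) - 19
  lv <- rep(1 + extra %/% 19, 19)
  rem <- extra %% 19
  if (rem > 0) lv[order[seq_len(rem)]] <- lv[order[seq_len(rem)]] + 1
  lv
}

# Split a UI SF total over (frequency 0-5, amount 0-6, impact 0-10),
# proportional to the item maxima with greedy remainder placement.
uisf_from_total <- function(total, maxima = c(5, 6, 10)) {
  total <- round(total)
  x <- floor(total * maxima / sum(maxima))
  while (sum(x) < total) {
    headroom <- maxima - x
    i <- which.max(headroom)
    x[i] <- x[i] + 1
  }
  x
}

# Gamma draws with given mean and CV; mean 0 gives exact zeros.
rgamma_mean_cv <- function(n, mean, cv) {
  if (mean == 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

# Rescale draws so the subset `idx` has exactly the target mean.
calibrate_continuous <- function(x, idx, target) {
  m <- mean(x[idx])
  if (m > 0) x[idx] <- x[idx] * target / m
  x
}

# Integer counts whose subset sum equals round(length(idx) * target):
# scale, floor, then hand out the remaining units by largest remainder.
calibrate_counts <- function(x, idx, target) {
  n <- length(idx)
  goal <- round(n * target)
  y <- x[idx]
  if (sum(y) > 0) y <- y * goal / sum(y)
  f <- floor(y)
  short <- goal - sum(f)
  if (short > 0) {
    give <- order(y - f, decreasing = TRUE)[seq_len(short)]
    f[give] <- f[give] + 1
  }
  x[idx] <- f
  x
}

#' Generate a synthetic two-arm trial
#'
#' Per participant, a latent severity (the LUTSqol total, drawn normal and
#' clamped to the 19-76 range) determines the baseline item levels through a
#' monotone spreading rule over a participant-specific item order; the
#' arm-specific treatment effect shifts the latent severity at follow-up and
#' the items are re-derived, so totals and the 9-item health state co-vary.
#' Resource use is drawn from gamma distributions (right-skewed,
#' non-negative) with the configured 4-week means; aid and laundry-load
#' counts are integers. One participant per arm drops out (their 3-month
#' record is absent) and, in the app arm, a configurable number of
#' completers has missing 3-month LUTSqol items.
#'
#' With `calibrate_means = TRUE` the completers' resource draws are
#' rescaled so each arm's observed mean equals the configured mean exactly
#' (continuous quantities by a common factor; counts by largest-remainder
#' rounding of the scaled draws). This mean-matched mode reproduces
#' arm-level published amounts from participant-level data; leave it off to
#' study sampling variability.
#'
#' @param config A [trial_config()].
#' @param calibrate_means Match completer arm means to the configured
#'   resource means exactly (default FALSE).
#' @return Object of class `synthetic_trial`: list with `participants`
#'   (tibble, one row per participant x available timepoint) and `config`.
#' @export
generate_trial <- function(config = trial_config(), calibrate_means = FALSE) {
  stopifnot(inherits(config, "trial_config"))
  participants <- withr::with_seed(config$seed, {
    arms <- names(config$n)
    arm_tbl <- purrr::map(arms, function(a) {
      n <- config$n[[a]]
      ids <- sprintf("%s%03d", a, seq_len(n))
      education <- ifelse(rbinom(n, 1, config$education_fraction[[a]]) == 1,
                          "university", "other")
      t1 <- pmin(76, pmax(19, round(rnorm(n, config$baseline_lutsqol_mean[[a]],
                                          config$baseline_lutsqol_sd[[a]]))))
      red <- round(rnorm(n, config$lutsqol_reduction_mean[[a]],
                         config$lutsqol_reduction_sd[[a]]))
      t2 <- pmin(76, pmax(19, t1 - red))
      u1 <- pmin(21, pmax(0, round(rnorm(n, config$baseline_uisf_mean[[a]],
                                         config$baseline_uisf_sd[[a]]))))
      # symptom change tracks the QoL change, rescaled to the 0-21 range
      u2 <- pmin(21, pmax(0, u1 - round((t1 - t2) * 11 / 34)))
      orders <- lapply(seq_len(n), function(i) sample.int(19))
      items1 <- t(mapply(items_from_total, t1, orders))
      items2 <- t(mapply(items_from_total, t2, orders))
      uisf1 <- t(vapply(u1, uisf_from_total, numeric(3)))
      uisf2 <- t(vapply(u2, uisf_from_total, numeric(3)))
      means <- config$resource_means_4wk[[a]]
      res <- lapply(c(baseline = 1, month3 = 2), function(tp) {
        list(pfmt_hours = rgamma_mean_cv(n, means[["pfmt_hours"]], config$resource_cv),
             laundry_hours = rgamma_mean_cv(n, means[["laundry_hours"]], config$resource_cv),
             aids = round(rgamma_mean_cv(n, means[["aids"]], config$resource_cv)),
             laundry_loads = round(rgamma_mean_cv(n, means[["laundry_loads"]], config$resource_cv)))
      })
      dropouts <- sample(ids, config$dropout_per_arm)
      completer_idx <- which(!(ids %in% dropouts))
      if (calibrate_means) {
        for (tp in c("baseline", "month3")) {
          res[[tp]]$pfmt_hours <- calibrate_continuous(
            res[[tp]]$pfmt_hours, completer_idx, means[["pfmt_hours"]])
          res[[tp]]$laundry_hours <- calibrate_continuous(
            res[[tp]]$laundry_hours, completer_idx, means[["laundry_hours"]])
          res[[tp]]$aids <- calibrate_counts(
            res[[tp]]$aids, completer_idx, means[["aids"]])
          res[[tp]]$laundry_loads <- calibrate_counts(
            res[[tp]]$laundry_loads, completer_idx, means[["laundry_loads"]])
        }
      }
      miss_qol <- if (a == "app" && config$missing_qol_app > 0) {
        sample(ids[completer_idx], config$missing_qol_app)
      } else character(0)
      make_rows <- function(tp, items, uisf, keep) {
        r <- res[[tp]]
        tb <- tibble::tibble(
          participant_id = ids, arm = a, education = education, timepoint = tp)
        it <- tibble::as_tibble(as.data.frame(items))
        names(it) <- lutsqol_items()
        tb <- dplyr::bind_cols(tb, it)
        tb$uisf_freq <- uisf[, 1]; tb$uisf_amount <- uisf[, 2]
        tb$uisf_impact <- uisf[, 3]
        tb$pfmt_hours_4wk <- r$pfmt_hours
        tb$laundry_hours_4wk <- r$laundry_hours
        tb$aids_4wk <- r$aids
        tb$laundry_loads_4wk <- r$laundry_loads
        tb[keep, ]
      }
      base_rows <- make_rows("baseline", items1, uisf1, seq_len(n))
      fup_rows <- make_rows("month3", items2, uisf2, completer_idx)
      fup_rows[fup_rows$participant_id %in% miss_qol, lutsqol_items()] <- NA_real_
      dplyr::bind_rows(base_rows, fup_rows)
    })
    dplyr::bind_rows(arm_tbl)
  })
  structure(list(participants = participants, config = config,
                 calibrated = calibrate_means),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  n <- x$config$n
  cat(sprintf("<synthetic_trial> app n=%d, control n=%d (seed %d%s)\n",
              n[["app"]], n[["control"]], x$config$seed,
              if (x$calibrated) ", mean-calibrated" else ""))
  print(dplyr::count(x$participants, .data$arm, .data$timepoint))
  invisible(x)
}

#' Recover per-arm summaries from a synthetic trial
#'
#' Arithmetic group means restricted to completers (participants with a
#' 3-month record); LUTSqol change additionally restricted to rows with
#' observed follow-up items. Resource means are taken from the 3-month
#' record except incontinence aids, which by the costing convention come
#' from baseline consumption (`aids_timepoint` overrides).
#'
#' @param trial A [generate_trial()] result, or its `participants` tibble.
#' @param aids_timepoint `"baseline"` (default) or `"month3"`.
#' @return One row per arm: ns, mean baseline/follow-up LUTSqol and UI SF
#'   totals, mean LUTSqol reduction, and mean 4-week resource use.
#' @export
recover_parameters <- function(trial, aids_timepoint = c("baseline", "month3")) {
  aids_timepoint <- match.arg(aids_timepoint)
  pp <- if (inherits(trial, "synthetic_trial")) trial$participants else
    tibble::as_tibble(trial)
  if (nrow(pp) == 0) abort("empty trial")
  scored <- score_lutsqol(score_uisf(pp), na_action = "omit")
  completers <- scored |>
    dplyr::count(.data$arm, .data$participant_id) |>
    dplyr::filter(.data$n == 2)
  if (nrow(completers) == 0) abort("no completers in some arm")
  cc <- dplyr::semi_join(scored, completers, by = c("arm", "participant_id"))
  wide <- cc |>
    dplyr::select(dplyr::all_of(c("arm", "participant_id", "timepoint",
                                  "lutsqol_total", "uisf_total",
                                  "pfmt_hours_4wk", "laundry_hours_4wk",
                                  "aids_4wk", "laundry_loads_4wk"))) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("lutsqol_total", "uisf_total",
                                       "pfmt_hours_4wk", "laundry_hours_4wk",
                                       "aids_4wk", "laundry_loads_4wk"))
  aids_col <- paste0("aids_4wk_", aids_timepoint)
  wide |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_completers = dplyr::n(),
      mean_baseline_lutsqol = mean(.data$lutsqol_total_baseline, na.rm = TRUE),
      mean_month3_lutsqol = mean(.data$lutsqol_total_month3, na.rm = TRUE),
      mean_lutsqol_reduction = mean(
        .data$lutsqol_total_baseline - .data$lutsqol_total_month3, na.rm = TRUE),
      mean_baseline_uisf = mean(.data$uisf_total_baseline),
      mean_pfmt_hours_4wk = mean(.data$pfmt_hours_4wk_month3),
      mean_laundry_hours_4wk = mean(.data$laundry_hours_4wk_month3),
      mean_aids_4wk = mean(.data[[aids_col]]),
      mean_laundry_loads_4wk = mean(.data$laundry_loads_4wk_month3),
      .groups = "drop"
    )
}
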