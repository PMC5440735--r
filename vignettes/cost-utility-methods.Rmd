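---
title: "Methods: a deterministic 1-year cost-utility analysis of app-based PFMT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a deterministic 1-year cost-utility analysis of app-based PFMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcua)
```

## The analysis

`trialcua` implements a deterministic cost-utility analysis comparing two
arms of a randomized trial — 3 months of app-guided pelvic floor muscle
training (PFMT) versus no treatment for stress urinary incontinence — over
a 1-year societal horizon. "Deterministic" means the economic result is a
function of arm-level means: no bootstrap, no probabilistic sensitivity
analysis, no confidence intervals around the ICER. Uncertainty is explored
instead through deterministic one-way and multiway scenarios on the cost
side.

The chain is:

1. score the ICIQ-LUTSqol (19 items, 1–4 each; total 19–76) and, where
   collected, the ICIQ-UI SF (3 items; total 0–21, banded none / slight /
   moderate / severe / very severe);
2. reduce 9 LUTSqol items to a health-state classification and map it to a
   utility weight in [0, 1] by an additive-decrement preference index;
3. build each arm's utility trajectory and compute QALYs by area under the
   curve;
4. annualize and value each arm's resource use into a six-component
   societal cost breakdown;
5. combine the arm summaries into ΔCost, ΔQALY, the ICER, and a
   cost-effectiveness-plane quadrant;
6. re-run step 5 under the scenario bundle.

## Utility weights and the placeholder index

The valuation algorithm for the condition-specific health state (derived
for the King's Health Questionnaire family of instruments) is applied in
the standard additive form

$$u = \max\!\big(\text{floor},\; b - \textstyle\sum_{i=1}^{9} d_i(\ell_i)\big),$$

with $d_i(1) = 0$ and $d_i$ non-decreasing in the level, which guarantees
that a worse answer can never raise the utility. The published coefficients
of that index are not in the public domain, so the package ships a
**synthetic placeholder** (`default_utility_config()`, also as
`extdata/utility_index_synthetic.yaml`): items 3–11, base value 0.99,
per-level decrements (0, 0.005, 0.011, 0.018) for every item, floor 0. Two
choices deserve justification:

* *Which 9 items*: not derivable from the instrument alone; items 3–11 are
  a neutral contiguous block covering the role/physical/social/emotional
  domains typical of such indices. Any real analysis must substitute the
  licensed item set via `read_utility_config()`.
* *Decrement scale*: chosen once so that a clinically relevant LUTSqol
  improvement of a few points maps to a utility gain of order 0.01 per
  year — the magnitude reported for conservative incontinence treatments
  (PFMT programmes and antimuscarinic drugs alike). Absolute utility
  *levels* from the placeholder carry no external meaning; only changes
  are interpretable, and then only in order of magnitude.

## QALYs

Each arm's trajectory has two assessments: linear change from baseline to
follow-up at $t$ = 0.25 yr, then constant to the horizon $h$ = 1 yr (the
stability assumption is supported by longer-term follow-up of comparable
internet-based PFMT programmes). The area under this piecewise-linear curve
is computed by the trapezoidal rule, which is exact for that shape; a test
suite cross-checks it against dense-grid numerical integration (grid
1e-4 yr, 200 random trajectories, agreement within 1e-6).

The **QALY gain** is defined relative to the baseline utility held
constant: gain $= (u_1 - u_0)(h - t/2)$. This is the only reading under
which a 3-month quality-of-life change produces gains of order 0.01 per
year, and it is what "changes in utility weights reflect gains in QALYs"
means operationally. `implied_utility_change()` inverts the geometry
(gain $/ (h - t/2)$), which is how a published QALY gain is translated back
into a follow-up utility change when participant-level utilities are not
recoverable. Days-in-full-health equivalents use 365.25 days/year; with
that convention an annual gain of 0.01006 corresponds to about 3.67 days
(a published rounding of ~3.9 days for the same quantity is not exactly
reproducible under any day-count convention we tried; we report the
365.25-day conversion).

No discounting is applied: the horizon is one year.

## The cost model

Six components, euro at 2013 year-end prices (1 EUR = 8.94 SEK):

| component | unit price (default) | source quantity |
|---|---|---|
| assessment | 6.4 € /participant | fixed per participant |
| treatment delivery | 0 € | none identified for the app |
| PFMT time | 29.61 € /h | 4-week self-report, annualized with maintenance blend |
| laundry time | 29.61 € /h | 4-week self-report, annualized constant |
| incontinence aids | 0.134 € /unit | 4-week count, annualized constant |
| extra laundry loads | 2.21 € /load | 4-week count, annualized constant |

Annualization multiplies 4-week quantities by 365.25/28 ≈ 13.045. For the
treated arm's PFMT hours the reported rate reflects the active prescription
(21 sessions/week); after month 3 the prescription drops to maintenance
(2.5 sessions/week, midpoint of "2 or 3"), so annual hours are scaled by
$f + (1-f)m$ with $f = 3/12$ and $m = 2.5/21$. This session-ratio blend is
the most literal reading of "participants follow the maintenance
prescription"; both rates and the treatment duration are configurable in
`annualization_policy()`. The untreated arm's rate is assumed constant all
year. A note on the assessment cost: 6.4 € is the figure in the cost table
itself; a variant figure of 6.3 € appearing in surrounding discussion is
treated as a typographical artefact.

Aid consumption enters the costing from the **baseline** assessment by
default (`aids_timepoint`), matching the convention that aid use was priced
at baseline consumption while time and laundry come from follow-up; the
timepoint is configurable because the convention is ambiguous.

Participant time is valued at gross hourly wages matched on education.
The default wage table carries the cohort-mean wage (29.61 €/h) for both
strata — the arm-level analysis only ever used the single cohort figure —
but `price_config()` accepts arbitrary stratified wage tables.

## Incremental analysis and sensitivity

`incremental()` computes ΔCost, ΔQALY and their ratio, and classifies the
comparison on the cost-effectiveness plane. Two deliberate conventions:

* ΔQALY = 0 yields an *undefined* ICER (`NA` plus a note), never ±Inf.
* A negative ICER is never reported bare: SE (cheaper and more effective,
  "dominant") and NW (more costly and less effective, "dominated") both
  produce negative ratios, so the quadrant and a dominance label always
  accompany the number.

`judge_willingness_to_pay()` defaults to 11,200 €/QALY (100,000 SEK, the
conventional "low incremental cost" anchor in Sweden); SW comparisons are
judged by the symmetric rule (savings per QALY forgone must meet the
threshold).

Scenarios (`scenario()`, `apply_scenario()`, `run_sensitivity()`) are
cost-side only — they scale or exclude components of both arms' breakdowns
identically and never touch the QALY entries. The bundled bundle holds the
four standard cases: PFMT time halved, laundry cost halved, laundry time
excluded, and the multiway combination. "Laundry cost halved" means the
per-load goods cost, distinct from laundry *time*; this reading is fixed by
arithmetic (halving the loads component reproduces the published scenario
totals, halving laundry time does not).

## Reproducing published tables: rounding provenance

A published cost table is self-consistent at 0.1 € precision (the printed
total equals the sum of the printed components) but is generally *not*
reproducible at that precision from the printed unit prices and amounts —
e.g. 114.40 aids × 0.134 € = 15.33 €, printed 15.4 €; 15.66 h × 29.61 € =
463.69 €, printed 463.7 €. The original analysis clearly carried unrounded
participant-level intermediates that are not recoverable. The package
therefore distinguishes two entry points:

* `cost_breakdown_from_amounts()` — amounts × prices, unrounded; totals
  land within 0.2 € of the published ones and components within 0.1 €.
* `cost_breakdown()` with printed component costs — the self-consistent
  arm-level inputs (`extdata/arm_inputs.yaml`); this is the route for
  reproducing the incremental and sensitivity tables, where the
  scenario with the smallest ΔCost (PFMT time halved: ΔCost ≈ −20.6 €) is
  sensitive to 0.1 € component rounding. ΔQALY is taken as the unrounded
  difference of the arm gains (0.01006 − 0.00158 = 0.00848; a printed
  ΔQALY of 0.00849 again reflects unrounded upstream values). All five
  ICERs then agree with the published figures within 0.2 %.

Display rounding (costs 1 dp, QALYs 5 dp, ICERs 1 dp) is left to the
report layer; all computation is double precision throughout.

## The synthetic trial generator

`generate_trial(trial_config())` emulates the trial's structure: arm sizes
62/61, one dropout per arm, three app-arm completers with missing follow-up
LUTSqol items, education mix 84 % / 75 % university, baseline LUTSqol
34.1/34.8 (SD 6.1), mean 3-month reductions 4.8/0.7, baseline UI SF
11.1/11.0, and 4-week resource-use means chosen so the annualized arm means
equal the published annual amounts.

Mechanics and the assumptions they encode:

* *Latent severity*: each participant's LUTSqol total is drawn normal
  (rounded, clamped to 19–76) and spread over the 19 items by a monotone
  allocation along a participant-specific random item order, held fixed
  across timepoints. Totals and the 9-item health state therefore co-vary,
  and follow-up change moves individual items gradually. The generator does
  not model per-item response styles, floor/ceiling clustering, or
  item-level measurement error.
* *Dispersions not reported in the study*: reduction SDs are back-derived
  from the reported 95 % CIs (app 3.4–6.2 → SD ≈ 5.4; control −0.5–1.8 →
  SD ≈ 4.6); resource use uses gamma draws with coefficient of variation
  0.8 (right-skewed, non-negative — an assumption, flagged as such). Aid
  and load counts are rounded to integers.
* *UI SF follow-up change* is tied to the LUTSqol reduction by the ratio of
  scale locations (≈ 11/34); it is generated for completeness of the
  records and nothing downstream of scoring depends on it.
* *Missingness* is completely at random (the dropout and the item-missing
  subset are sampled uniformly), matching the completer-analysis design.

`calibrate_means = TRUE` additionally rescales the completers' resource
draws so each arm's observed mean equals the configured mean exactly
(continuous quantities by a common factor; integer counts by
largest-remainder rounding, so the arm mean is within 1/(2n) of target).
This mean-matched mode is what lets a participant-level run reproduce
arm-level published amounts; with it off, arm means vary with sampling
error of order mean × 0.8/√n — tens of euro for the cost components — which
is the realistic regime for power or robustness studies.

What passing tests on synthetic data do **not** show: that the placeholder
utility index approximates the licensed one, that real response patterns
follow the latent-spread model, or that real resource use is gamma with
CV 0.8. They show the pipeline's arithmetic and plumbing are correct under
a data-generating process with the study's first moments.

## Problem sizes and numerical choices

The test suite runs the generator at the study size (123 participants) and
at 10× (1,230) for parameter-recovery checks; property sweeps use 20–200
random cases under fixed seeds; the AUC oracle uses a 1e-4-yr grid. These
sizes keep the whole suite in the seconds range while leaving Monte-Carlo
error well inside the asserted bounds (recovery checks assert within 2
standard errors; the null-effect check within 3). Degenerate inputs are
handled explicitly: ΔQALY = 0 → undefined ICER; `t_followup = horizon` →
no extrapolation segment; zero resource use → assessment-only cost; a
severity total of 0 sits below the published bands and is labelled
`none`; scenario factors must be positive, with `exclude` as the proper
way to zero a component (numerically identical to scale-by-0 in effect on
the total, and idempotent).

## Limitations

* The utility coefficients are placeholders; absolute QALY levels from
  participant-level mode are not externally meaningful.
* The maintenance blend for treated-arm PFMT hours cannot be validated
  against participant-level data; the group-mean input mode bypasses it
  where published annual amounts are available.
* One-year horizon with a single follow-up: the constant-extrapolation
  assumption does all the work beyond month 3.
* Cost-side sensitivity only, mirroring the deterministic design; no
  probabilistic sensitivity analysis or CEAC is provided (the scenario
  engine is the extension point).
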