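# trialcua

Deterministic, trial-based **cost-utility analysis** of app-delivered pelvic
floor muscle training (PFMT) for stress urinary incontinence (SUI), from a
1-year **societal perspective**. The package is aimed at health economists
and trialists who want the whole chain — questionnaire scoring → utility
weights → QALYs → annualized societal costs → incremental cost-effectiveness
→ deterministic sensitivity analysis — as composable, tested, pipe-friendly
R functions, plus a synthetic two-arm trial generator so everything runs
end-to-end without access to participant data.

## The model

Two arms are compared: 3 months of app-guided PFMT versus no treatment, with
assessments at baseline and 3 months extrapolated to 1 year.

**Effects.** Quality of life is measured with the 19-item ICIQ-LUTSqol
(items scored 1–4; total 19–76, higher = more impact). Nine items form a
health-state classification that a preference-based index maps to a utility
weight u ∈ [0, 1]. Each arm's utility trajectory changes linearly from
baseline to the 3-month assessment and is held constant for the rest of the
year; QALYs are the area under that curve, and the **QALY gain** is the area
between the curve and the baseline utility held constant:

```
QALY gain = (u_3mo − u_baseline) × (horizon − t_followup / 2)
```

**Costs.** Annual societal costs per participant sum six components:
assessment, treatment delivery (identically zero here), participant time for
PFMT and for extra laundry (valued at education-matched gross wages,
29.61 €/h), incontinence aids (0.134 €/unit) and extra laundry loads
(2.21 €/load). Four-week self-reports are annualized by 365.25/28; PFMT
hours in the treated arm are additionally scaled by the prescription blend
`f + (1 − f)·m` (f = treated fraction of the year, m = maintenance/treatment
session ratio) because training drops from 3 sessions/day to 2–3 per week
after treatment.

**Incremental result.** The arms are compared by the incremental
cost-effectiveness ratio ICER = ΔCost / ΔQALY, placed on the
cost-effectiveness plane (NE/SE/NW/SW, with SE = dominant), and judged
against a willingness-to-pay threshold (default 11,200 €/QALY). One-way and
multiway scenarios (halving PFMT time, halving laundry cost, excluding
laundry time) re-run the analysis deterministically.

## Worked example

Group-mean mode: feed the arm-mean cost breakdowns and QALY gains straight
into the analysis.

```r
library(trialcua)

inputs <- read_arm_inputs(system.file("extdata", "arm_inputs.yaml",
                                      package = "trialcua"))
report <- run_cua(arm_breakdowns = inputs$breakdowns,
                  qaly_gains = inputs$qaly_gains)
report
#> Base case: app vs control: dCost 64.6 EUR, dQALY 0.00848
#> ICER 7617.9 EUR/QALY  [NE]
#> acceptable at 11200 EUR/QALY: TRUE
glance(report)
#>   app_total_cost control_total_cost delta_cost delta_qaly  icer quadrant
#> 1            547               482.       64.6    0.00848 7618. NE
```

The app arm costs 64.6 € more per participant-year (mostly extra training
time) and gains 0.00848 QALYs more, i.e. about 7,618 € per QALY — well
under the 11,200 €/QALY "low cost" anchor, hence acceptable. `tidy(report)`
returns the five-row sensitivity table (base case plus four scenarios; the
ICER ranges from −2,423 €/QALY, where halving PFMT time makes the app arm
dominant, to 14,882 €/QALY when laundry time is excluded), and
`autoplot(report)` draws the cost-effectiveness plane.

Participant-level mode runs the same analysis from raw records:

```r
trial <- generate_trial(trial_config(seed = 42), calibrate_means = TRUE)
report <- run_cua(participants = trial$participants)
```

which scores every questionnaire, maps responses to utilities (the bundled
utility coefficients are a clearly-flagged synthetic placeholder — see the
vignette), annualizes and values each participant's resource use, and
averages by arm.

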