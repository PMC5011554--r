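# ergotherm

Objective monitoring of exercise-induced fatigue from training-device
thermometry.

A portable leg-training device dissipates the user's mechanical work as heat
in its resistance unit, so the exercise-induced temperature rise above the
session baseline (Δt°, °C, sampled once a minute and zeroed before each
session) is an objective proxy for leg work output (LWO). Recorded together
with heart rate (HR, BPM, minute-averaged, graded against
HRmax = 220 − age), the two signals separate exercise *intensity* from
exercise *output*, and fatigue becomes directly observable as their
dissociation:

* **fatigue onset** — the first minute at which LWO declines at steady HR,
  or HR rises at steady LWO;
* **fatigue-free bout** — steady LWO *and* steady HR for the entire
  exercise duration;
* **personalized dose** — the Δt° a participant reaches in a 30-minute
  fatigue-free bout of moderate-intensity continuous training (MICT);
  reaching that threshold on a later day "takes" the daily dose and fires a
  logged notification;
* **fatigability** — quantified retrospectively by how much longer the
  second half-dose (threshold/2 → threshold) takes than the first
  (0 → threshold/2).

The package is aimed at digital-health and exercise-physiology analysts who
want this measurement chain as reusable, tested code: a forward/inverse
thermal model of the device, a seeded synthetic-cohort generator emulating
the study conditions (7 participants, 30-min MICT at HR 100 (SD 10) BPM,
intensity-dependent fatigue onset, an evening fatigability effect), phase
segmentation and fatigue-onset detection, dose calibration/tracking, and the
grouped split-half statistics.

## The model in brief

Device temperature rise follows a first-order heating/cooling balance

    dΔ/dt = α·P(t) − λ·Δ(t),    Δ(0) = 0,

with work rate `P` in work-units/min (1.0 ≡ mean-participant moderate
intensity). High-sensitivity placement (λ = 0.4/min, α = 13.68) plateaus at
α·P/λ = 34.2 °C for P = 1; low-sensitivity placement (λ = 0.002/min,
α = 0.27818) rises quasi-linearly to 8.1 °C in 30 minutes — the unit daily
dose. `estimate_power()` inverts the model to recover the LWO signal that
fatigue detection operates on. Fatigue onset is planted (and detected)
linearly in the heart-rate deficit: ~7 min at HR 130, ~15 min at HR 120,
beyond the bout at HR 100; evening sessions advance onset and steepen the
post-onset decline, lengthening second half-doses by ~50 %. The methods
vignette (`vignettes/fatigue-monitoring.Rmd`) derives every default.

## Worked example

```r
library(ergotherm)
res <- run_study(seed = 1)

res$doses$mean
#> [1] 8.042857
res$notifications_15day
#> [1] 11
res$diurnal$groups[, c("group", "n", "mean_total", "percent_longer", "p_within")]
#>       group  n mean_total percent_longer     p_within
#> 1 afternoon 20     28.140       3.030303 3.723254e-01
#> 2   evening 20     35.825      54.710274 4.061521e-09
```

Reading the output: the seeded 7-participant cohort calibrates to a mean
personalized dose of ~8 °C (the Δt° reached in 30 fatigue-free moderate
minutes). Over the 15-day home program with 4 rest days, the dose threshold
fires 11 notifications — one per trained day. In the diurnal comparison of
the home participant's dose-taking bouts, afternoon sessions finish in ~28
minutes with statistically indistinguishable half-dose times (fatigue-free),
while evening sessions need ~36 minutes because the second half-dose runs
~55 % longer than the first (Welch P < 0.001) — the evening fatigability
pattern.

Individual pieces are exposed as ordinary functions: `simulate_bout()`,
`segment_phases()`, `detect_fatigue()`, `calibrate_dose()`, `track_dose()`,
`diurnal_compare()`, `compliance_summary()`, `generate_fixtures()`. A thin
command-line wrapper (`inst/cli/ergotherm.R`, or `ergotherm_cli()` from R)
exposes `simulate`, `segment`, `dose`, `report` and `fixtures` subcommands
over CSV/JSONL files.

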