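---
title: "Measuring the contribution of walking to work to daily physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the contribution of walking to work to daily physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Active commuting — walking or cycling for transport — is one of the few
forms of physical activity that fits naturally into an adult working day.
Quantifying how much the walk to work actually contributes to a person's
daily activity requires objective measurement: waist-worn accelerometers
give a time-resolved record of movement intensity but no context, and GPS
receivers give location but no intensity. `commutePA` implements the
combined analysis: accelerometer data reduction, timestamp-level merging
with GPS, automatic segmentation of home–work journeys, travel-diary
classification of commuters into usual modes, and the comparative
statistics that contrast walkers with car commuters.

Because no public dataset accompanies this design, the package also ships a
synthetic cohort generator whose ground truth makes every stage testable:
each quantity the pipeline estimates (non-wear time, journey windows,
MVPA minutes, travel modes, group effects) is injected by the generator and
can be compared against what the pipeline recovers.

# Accelerometer data reduction

The pipeline consumes epoch-level counts (timestamped sums of accelerometer
output over fixed bins, 10 s by default). The stages, with their tunable
parameters in `cut_point_config()`:

* **Reintegration** (`reintegrate()`): finer epochs are summed into coarser
  ones; counts are conserved exactly and a trailing partial window is
  dropped with a message.
* **Non-wear detection** (`detect_nonwear()`): a maximal run of zero-count
  epochs lasting at least `nonwear_min_minutes` (default 20, boundary
  inclusive) is non-wear. The run must be strictly continuous — a single
  positive count terminates it; no "spike tolerance" is applied because the
  definition is a continuous zero period. Runs are found on the full day
  stream *before* the analysis window is applied, so a run straddling the
  06:00 boundary still counts its full length.
* **Intensity classification** (`classify_intensity()`): thresholds are in
  counts per minute (cpm) and scaled to the epoch by `epoch_s / 60`.
  Both inequalities are strict: MVPA requires counts *above* 1952 cpm,
  sedentary *below* 100 cpm; counts exactly at either cut-point are light.
  At 10-s epochs the MVPA bound is 1952/6 ≈ 325.3, so 326 counts is MVPA.
* **Daily summaries** (`summarise_day()`, `summarise_days()`): restricted
  to the half-open window `[06:00, 24:00)` (an epoch belongs iff its start
  time does), non-wear removed, then wear minutes, mean cpm
  (total counts ÷ wear minutes), MVPA and sedentary minutes, and the
  valid-day flag (wear ≥ 600 minutes, boundary inclusive). A day with zero
  wear yields `mean_cpm = NA` and `valid = FALSE`, never a division error.
  Days are calendar dates in naive local time; Saturday and Sunday are
  weekend. The cpm denominator is wear minutes (standard practice; the
  alternative window-minutes denominator would be a one-line change in
  `summarise_days()`).

# Journey segmentation

`merge_acc_gps()` merges the two streams on the accelerometer's timestamps:
every epoch is retained and paired with the nearest fix within 5 s, fixes
never create epochs, and unmatched fixes are discarded with a count.

`segment_journeys()` replaces manual map inspection with an explicit
algorithm. Within each commute window (06:00–10:00 and 16:00–20:00 by
default), a journey is a run of position-bearing epochs that starts inside
one anchor's geofence (100 m default radius around the geocoded home or
workplace) and ends inside the other's, with no internal position gap over
5 minutes — the operationalisation of a "continuous or near-continuous"
sequence of locations between home and work. When several anchor-to-anchor
candidates exist, the longest wins and ties break to the earlier start.
Direction is purely geometric (which fence the run starts in); the diary is
never consulted for segmentation. Mid-route stationary stops — shop visits
on the way home — are *retained inside* the journey, detected as lagged
displacement below 0.6 m/s outside both geofences accumulating to at least
3 minutes (a total-time rule rather than one unbroken run, so a single
noisy fix cannot hide a stop). The geofence radius and gap tolerances are
configuration, chosen to tolerate urban GPS error and brief signal loss.

Distances are great-circle (haversine) on WGS84, accurate to well under
0.5% at commute scales.

`commute_contribution()` reports, per participant, mean daily journey MVPA
over mean daily total MVPA (06:00–24:00, valid weekdays). The cohort
headline is the **ratio of cohort means** — the printed arithmetic of the
published figure (38.0 of 80.3 minutes) identifies that form — and the mean
of per-participant ratios is reported alongside.

# Cohort classification

A diary day contributes a mode only when the same non-missing mode was
reported both to and from work. A participant's usual mode is the mode with
the most such days; with zero classifiable days the baseline questionnaire
is used; a tie has no majority and is classed `mixed_other` (the only
consistent home for it, since no tie-breaking rule is defined in the
field's practice). Usual cyclists are excluded because waist-worn
accelerometers under-record cycling, as are mixed/other participants and
anyone without a valid accelerometer day. `build_analysis_set()` emits a
flow report whose bins exactly partition the cohort.

# Statistics

Group contrasts are one-way ANOVA (`compare_groups()`; for two groups
F = t² of the equal-variance t-test). Weekday–weekend contrasts are paired
t-tests on per-participant means. The adjusted analysis
(`fit_adjusted_model()`) is OLS on one row per participant — weekday means
— with travel mode (car reference) adjusted for sex (male reference), age,
education (degree vs not), income (≤ vs > £30,000), occupational activity
(sedentary vs not), work status (part- vs full-time) and accelerometer wear
time; a participant-level model is used because a single wear-time
covariate per participant implies it, and day-level rows would require
cluster corrections the design does not call for. Covariates with no
variation in the analysed cohort are dropped with a message (they cannot be
adjusted for); genuine collinearity and a single-mode cohort are errors.
Normality is assumed; p-values are two-sided; no multiple-testing
correction is applied. The day-level comparison pools all walking days
against all car days regardless of the participant's usual mode.

# The synthetic cohort generator

`generate_cohort()` emulates a UK workplace cohort of adults living within
walking distance of work, measured for 5 weekdays and 2 weekend days:

* **Commutes**: one-way durations 19.7 ± 8.3 min on foot and
  10.7 ± 7.6 min by car (the study conditions); departures around 08:20 and
  17:10; waypoint polyline routes (no street network) walked at ~4.8 km/h.
* **Counts**: generated directly at epoch level — the analysis consumes
  reintegrated epochs, so a raw 30 Hz signal would add nothing testable.
  Each waking minute gets an intensity state; a minute-level cpm is drawn
  and epoch counts are Poisson around the per-epoch rate. Background states
  follow an hourly mean-cpm profile (`default_background_profile()`):
  an "active" fraction of minutes, split 18% MVPA-intensity and 82% light,
  reproduces desk-worker volumes of roughly 45–50 background MVPA minutes
  per day. Walking minutes draw from `walk_intensity_cpm`
  (4000 ± 600 cpm by default — a parameter, not a claim, since no reference
  distribution of walking counts exists). MVPA-bearing states are truncated
  above 2400–2600 cpm and sub-sedentary states below 90 cpm, so the
  injected MVPA minutes are recoverable to within a fraction of a minute
  per day; this is what makes ±1-minute recovery checks meaningful.
* **Wear**: waking-hours wear (~07:10 to ~22:25) with ~1.5 removal runs of
  25–90 zero minutes per day. Mean daily wear (~820 min) is somewhat above
  typical field studies (~720 min); this inflates absolute sedentary/MVPA
  volumes slightly and affects no comparison the package tests.
* **GPS**: 10-s fixes along the route with 5 m isotropic jitter and 2% fix
  dropout; weekends have no commutes and a flattened background profile.
  A homeward journey includes a stationary mid-route stop of 4–10 minutes
  with probability `detour_probability` (0.4), emulating shop visits that
  lengthen the journey home without adding MVPA.
* **Diaries and demographics**: 95% of weekdays use the participant's usual
  mode, 3% of entries are missing, 5% of participants return no diary (90%
  of those have a questionnaire mode). Demographic bands are sampled from
  the marginal distributions typical of such cohorts. These rates make the
  usual-mode classifier's ground-truth recovery ≥ 95% by construction,
  which is the calibration the recovery tests assume.
* **Reproducibility**: one global seed fans out to per-participant child
  seeds (`seed * 48271 + i * 10007 mod 2^31 − 1`), so cohorts are
  bit-identical under a fixed seed and reproducible participant by
  participant.

**Calibration mode** (`mode_effect_cpm`): parameter-recovery studies need a
*known* travel-mode effect, but the generator's natural effect is emergent
(commute minutes × walking intensity). Setting `mode_effect_cpm` makes
walkers behaviourally identical to car users (car commute durations and
intensities, no detours) and shifts every worn minute of their counts by
the given constant, so the true regression coefficient is exact.

What the generator does **not** emulate: street-network routing, raw 30 Hz
or triaxial signals, seasonal or weather effects, urban canyon GPS
multipath (jitter is isotropic Gaussian), device clock drift, or
behavioural correlation between demographics and activity (covariates are
independent of the outcome, which is exactly what makes adjusted-model
recovery unbiased but means confounding structure is not exercised).
Passing recovery tests therefore demonstrates the pipeline's correctness on
data with the assumed structure, not robustness to every field artefact.

# Validation sizes and numerical choices

The shipped checks use: 1000 random count sequences against a brute-force
maximal-zero-run scanner; 100 random mini-days against an exhaustive
anchor-to-anchor journey search; 100 calibration cohorts of n = 50 (5
weekdays) for CI coverage of a +150 cpm injected effect; one default cohort
of n = 50 for the qualitative pattern suite. These sizes give stable
verdicts in a few minutes on a single core; larger cohorts change nothing
but runtime. All timestamps are naive local time by contract (no DST
arithmetic); epoch membership in any window is decided by the epoch's start
time; the analysis window and commute windows are half-open.

# Known limitations

* Journey segmentation assumes the commute reaches both geofences; a trip
  abandoned mid-way or a workplace visit outside the commute windows is not
  counted.
* The 47.3%-style contribution is sensitive to the denominator population
  (participants with at least one segmented journey); both the ratio of
  means and the mean of ratios are reported.
* No 10-minute-bout MVPA accounting, energy-expenditure estimation, or
  non-wear imputation; cycling days are excluded rather than corrected.
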