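---
title: "Methods: linking wearable sleep and HRV features to momentary self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking wearable sleep and HRV features to momentary self-reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emawear)
```

## The problem this package addresses

Consumer wrist devices record sleep episodes, minute-level activity (steps,
METs) and pulse rate at a 5-second cadence over weeks of free-living wear,
while ecological momentary assessment (EMA) samples momentary states —
sleepiness, mood, energy on 0–100 visual analog scales (VAS) — a few times a
day. `emawear` implements the full analysis chain for a study of this design
in office workers: wear-validity filtering, per-night sleep consolidation,
windowed SDNN heart-rate variability, joining each EMA response to its
prior-hour activity and previous-night sleep, quartile-based nonparametric
contrasts against stress/well-being questionnaires (PSS, SWLS, SPANE-P/N,
FS-J, JESS), and person-mean-centered linear mixed models.

Because no such device/EMA dataset is public, the package ships a synthetic
cohort generator with a fully documented ground truth, so every downstream
stage is testable and the whole pipeline's ability to recover known effects
can be measured.

## Feature derivation

### Sleep nights

Raw device sleep records (`bed_start`, `bed_end`, `minutes_asleep`) are
grouped by wake-anchor date and consolidated per night: time in bed (TIB) is
the length of the *union* of in-bed intervals (split nights are merged
without double counting), sleep duration the summed asleep minutes capped at
TIB, sleep efficiency `100 * sleep / TIB`, and bedtime/midpoint encoded as
continuous minutes after noon of the onset day so that times wrap correctly
across midnight (23:21 → 681; 02:36 → 876). The midpoint is the temporal
midpoint of the consolidated span: the device reports in-bed endpoints, not
within-record sleep placement, so a sleep-weighted midpoint is not
identifiable from the export and was rejected.

Sleep regularity is the sample SD of the nightly midpoint within consecutive
7-day blocks counted from the study start (enrollment-anchored, since
calendar weeks would split participants' first block); weeks with fewer than
3 nights yield a missing SD because an SD of two points is uninformative.
Both choices are function arguments.

### Wear validity

"Worn" is defined at minute resolution — a minute counts if at least one
pulse sample falls in it — because the device's own wear detection is not
exported. The three filters keep the literal inclusivity of their
definitions: a valid record day needs *at least* 80% coverage (inclusive),
the hour before an EMA response needs coverage *exceeding* 80% (strict, so
48/60 fails), and the overnight window from 18:00 the day before to 09:00
needs *80% or greater* (inclusive, so 720/900 passes). Observations — not
participants — are filtered, each filter gating only the features it
protects (prior-hour aggregates vs previous-night sleep).

### SDNN from 5-second pulse samples

The device exports a rate every 5 s rather than beat-to-beat intervals, so
NN intervals are approximated as `60000 / bpm` ms and SDNN is the sample SD
(n−1) of those values within 15-minute windows aligned to clock
quarter-hours (the alignment is a package convention). Windows with fewer
than 144 of the nominal 180 samples (80%, mirroring the wear logic) are
missing. A window is labeled *sleep* when its midpoint lies inside a
consolidated in-bed interval; nightly summaries average the night's valid
sleep-window SDNNs (per-night-then-per-person aggregation). This is an
approximation to ECG SDNN, adequate for within-study contrasts, not for
comparison with beat-accurate norms.

### EMA linkage

Only prompts answered on their scheduled day enter the observation table.
Prior-hour aggregates use the half-open window `[t − 60 min, t)` anchored at
the *response* time (the scheduled-time anchor is available as an option);
the previous night is the consolidated night waking between 18:00 the day
before and 09:00 of the response date, endpoints closed.

## Statistical analysis

### Quartile contrasts

Participants are split on each questionnaire at the interpolated (type-7)
quartiles, inclusive on both boundaries; a degenerate split (Q1 = Q3) is an
error. Group differences use a Mann–Whitney U test with tie-corrected
variance and 0.5 continuity correction, switching to full enumeration of the
permutation distribution when the combined sample size is at most 12.
Bonferroni adjustment uses the number of metrics actually compared per
instrument (recorded in the output, since the original family is not
recoverable). Effect sizes are `r = Z / sqrt(N)` and Hedges g.

Two numerical facts matter here. First, by exhaustive enumeration the
continuity-corrected normal approximation differs from the exact two-sided p
by up to 0.088 at group sizes (2, 2) and by more than 0.02 whenever either
group has fewer than 4 observations; agreement within 0.02 holds once both
groups have ≥ 4 values and the combined size is ≥ 11. The exact branch is
therefore the one used at those sizes. Second, the *unit of analysis* for
the contrasts: pooling night-level values within each quartile group matches
how group medians of nightly bedtime are usually reported, but it treats the
~14 nights of one participant as independent. Because sleep timing varies
substantially between persons (bedtime intraclass correlation ≈ 0.45 in the
generator's default world), the pooled test is anticonservative under the
null — simulation puts its realized size near 0.13 after Bonferroni rather
than 0.05. `run_quartile_analysis(unit = "participant")` compares
per-participant means instead and is calibrated; the pooled default is kept
for comparability, with this caveat.

### Multilevel models

Each time-varying nightly index is decomposed into the participant's own
mean (between-person, "interindividual") and the deviation from it
(within-person, "intraindividual"). The published description of the
between-person component ("the mean value across all participants") only
makes sense per participant — a single grand mean carries no between-person
information — so standard person-mean centering is the implemented reading;
this is the major interpretation choice in the package.

Outcomes and continuous predictors are standardized over the included
observations (gender stays 0/1; response time enters as the standardized
prompt-slot index 1–4, clock minutes optional), so estimates are unit-free
like the printed tables. Models are random-intercept linear mixed models
with the published random-slope structure — response time and METs for all
outcomes, plus the outcome-specific nightly deviation (sleep heart rate for
energy, midpoint for mood, TIB for sleepiness) — fitted by maximum
likelihood so AICs are comparable during forward stepwise selection
(controls always retained; candidates added while AIC strictly decreases;
complete cases over all candidate columns so every step sees the same
likelihood support). Random slopes are fitted *uncorrelated* with the
intercept (`||`): with 40–60 participants, free slope-intercept covariances
frequently hit the boundary, and the published tables do not specify the
covariance structure. CIs and p-values are Wald-normal at the 95% level
(the published level is unstated); non-convergence triggers up to three
perturbed restarts and is flagged, never silenced. The unconditional
intraclass correlation is `var_intercept / (var_intercept + var_residual)`
from `outcome ~ 1 + (1 | participant)`.

Collinearity caveat: the nightly indices are strongly dependent by
construction (midpoint = bedtime + span/2; sleep duration ≈ TIB ×
efficiency). Entering all between- or within-components jointly splits
coefficients arbitrarily; the stepwise selector typically keeps one of each
near-collinear pair, and recovery checks therefore target the selected
(printed-table) structure rather than a saturated fit.

## The synthetic cohort: what it emulates and what it does not

`gen_config()` states the emulated world. Defaults: prompts at 09:00, 12:00,
15:00, 18:00 on 8 study days; nonresponse 12.66% (an 87.34% response rate);
lognormal response latency with median 11.8 minutes (sdlog 1.9 matches the
reported 3.2–42.4 IQR); 12% of minutes unworn (≈ 88% recovery); bedtime ~
Normal(chronotype, regularity_sd) with chronotype centred at 23:30 (SD 45
min) and per-person regularity SD uniform on 20–80 min; TIB ~ Normal(480,
45) min; nights split into two records with probability 0.1 (the true split
frequency is unreported, so it is a free parameter); sleeping heart rate
centred per person (62 ± 6 bpm) with a per-night offset of SD 3 bpm — the
ground truth behind the "deviation of heart rate during sleep" predictor —
and 2 bpm sample noise. The test-scale default is 8 participants × 14 days;
`paper_scale = TRUE` gives 40 × 56 with EMA days in weeks 1–2 and 7–8.

Latent EMA outcomes follow the multilevel model the analysis assumes:
`y = γ'z + b_i + e`, with standardized slope defaults −0.12 (within-person
sleep-HR deviation on energy), −0.26 (between-person midpoint on energy) and
−0.10 (within-person TIB on sleepiness); mood has no structural slope. The
variance weights `var_intercept`/`var_residual` (defaults 0.69/1) are
treated as a ratio and rescaled so the latent outcome has unit total
variance — this keeps the generating slopes on the standardized scale the
models estimate, and makes the null-slope intraclass correlation exactly
0.69/1.69 ≈ 0.408. The VAS mapping is `round(50 + 20·y)` clipped to
[0, 100], keeping typical values mid-scale; clipping affects ≈ 5% of
draws and attenuates variances by a percent or two, which the recovery
tolerances absorb.

Questionnaire scores are monotone in latent stress, chronotype and each
participant's realized weekly midpoint SD (later bedtime ⇒ higher PSS/JESS,
lower SWLS; larger midpoint SD ⇒ higher PSS, lower FS-J/SPANE-P), with
Gaussian noise, rounded and clipped to instrument ranges.

The generator does *not* emulate sleep stages, naps outside the 18:00–09:00
window, glucose or diet data, autocorrelated wear gaps, circadian weekday/
weekend structure, or device firmware quirks. A green recovery test
therefore establishes that the pipeline recovers effects under the stated
model — not that the device's own measurement error behaves this way.

What recovery looks like in practice (60 participants × 28 days, printed-
table model structure): the within-person slopes come back essentially
unbiased while the between-person midpoint slope attenuates toward ≈ −0.20
from −0.26 because the person mean is estimated from ~8 matched nights whose
night-to-night variability (bedtime SD up to 80 min) inflates the empirical
between-person SD; its 95% CI still covers the generating value at roughly
the nominal rate.

## Numerical conventions and degenerate inputs

Timestamps are timezone-naive local time (stored as UTC POSIXct, serialized
ISO 8601) — the study site has no daylight-saving shifts. Sample SDs use the
n−1 denominator throughout. Empty coverage intervals, empty record lists,
constant vectors passed to `standardize()`, zero pooled SDs in Hedges g and
degenerate quartile splits raise errors; under-observed windows and weeks
return missing values instead. Loaders reject invalid rows into a parse
report by default (`strict = TRUE` aborts), because real exports contain
gaps. All `simulate_*` stages derive independent RNG streams from the
single config seed, so each stage and the full study are reproducible
byte-for-byte.

## Known limitations

- NN intervals derived from 5-second rate samples underestimate true
  beat-to-beat variability; SDNN values are internally comparable only.
- The pooled quartile contrast is anticonservative for between-person
  metrics (above); use `unit = "participant"` when calibration matters.
- Wald p-values are anticonservative at very small cluster counts.
- The generator's traits are Gaussian and its couplings linear; it cannot
  falsify distributional robustness claims.
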