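# emawear

Analysis pipeline linking consumer wrist-device data to ecological
momentary assessment (EMA) in free-living cohorts.

Office workers wearing a wrist device for several weeks generate three data
streams — in-bed sleep records, minute-level activity (steps, METs), and
pulse rate every 5 seconds — while EMA prompts at 09:00/12:00/15:00/18:00
collect momentary **sleepiness, mood and energy** on 0–100 VAS scales, and
stress/well-being questionnaires (PSS, SWLS, SPANE-P/N, FS-J, JESS) are
scored at baseline. `emawear` implements the full chain from raw tables to
the published-style results:

- **Wear validity**: minute-resolution coverage and the three 80% filters
  (valid record day ≥ 80%, pre-EMA hour > 80% strict, overnight
  18:00–09:00 window ≥ 80%).
- **Sleep features**: per-night consolidation by interval union (split
  nights merged without double counting), bedtime/midpoint encoded as
  minutes after noon, sleep efficiency `100 × sleep duration / TIB`, and
  weekly midpoint-SD regularity.
- **HRV**: SDNN per 15-minute window from 5-second pulse samples via
  `NN ≈ 60000 / bpm`, split into sleep/wake context, with nightly
  summaries.
- **EMA linkage**: each same-day response joined to its prior-hour
  `[t − 60 min, t)` activity aggregates and its previous night
  (wake in 18:00–09:00), gated by the wear filters.
- **Group statistics**: quartile split on each questionnaire (low = minimum
  to Q1, high = Q3 to maximum), Mann–Whitney U (exact enumeration at
  n₁+n₂ ≤ 12, tie-corrected continuity-corrected normal otherwise),
  Bonferroni adjustment, effect sizes `r = Z/√N` and Hedges g.
- **Multilevel models**: person-mean centering into between-person
  ("interindividual") and within-person ("intraindividual") components,
  unconditional ICCs, and random-intercept + random-slope linear mixed
  models (lme4, ML) with forward stepwise AIC selection, outcomes and
  predictors standardized:
  `y_it = β'x_it + γ_b x̄_i + γ_w (x_it − x̄_i) + b_i + e_it`.
- **Synthetic cohort**: a generator with documented ground truth
  (standardized slope defaults −0.12, −0.26, −0.10; variance ratio
  0.69/1, i.e. a null-slope ICC of 0.408; 87.34% response rate; 88% wear)
  so the whole pipeline is testable without any device export.

## Worked example

Simulate a cohort, derive features, and check adherence:

```r
library(emawear)
cfg   <- gen_config(seed = 1)                     # 8 participants x 14 days
study <- simulate_study(cfg, streams = TRUE)
nights <- consolidate_nights(study$sleep_records)
cov <- daily_coverage(study$heart_rate, dates = as.Date("2022-02-01") + 0:14)
adherence_summary(study$ema, cov, n_participants = 8, n_days = 15)
#> EMA response rate: 85.16% (218/256)
#> Response latency: median 13.3 (IQR 3.5-41.1) minutes
#> Device recovery rate: 87.94% (151,963/172,800 minutes)
#> Mean daily wear time: 1266 (SD 14) minutes
```

The response rate estimates the generator's configured 87.34% (12.66%
nonresponse) and the recovery rate its 12% non-wear; wear time is minutes
per day with at least one pulse sample.

Fit the energy model at a scale where the generating slopes are
identifiable (40 participants × 28 days, using the generator's nightly
cardiac truth):

```r
cfg    <- gen_config(n_participants = 40, n_days = 28, seed = 1)
traits <- generate_cohort(cfg)
sleep  <- simulate_nights(traits, cfg)
truth  <- attr(sleep, "truth")
ema    <- simulate_ema(traits, truth, cfg)
act    <- simulate_activity(traits, truth, cfg, days = cfg$ema_days)
obs <- build_observation_table(ema, act, NULL, consolidate_nights(sleep),
                               truth_night_cardiac(truth),
                               traits[, c("participant_id", "age", "gender")])
for (v in c("mean_sleep_hr", "midpoint")) obs <- decompose(obs, v)
for (v in c("age", "slot", "met_sum_1h", "mean_sleep_hr_within", "midpoint_between"))
  obs[[v]] <- standardize(obs[[v]])
obs$energy <- standardize(obs$energy)
fit_mixed(obs, "energy",
          c("age", "gender", "met_sum_1h", "slot",
            "mean_sleep_hr_within", "midpoint_between"),
          random_slope_terms = c("slot", "met_sum_1h", "mean_sleep_hr_within"))
#>            Predictors Estimates             CI P value
#>           (Intercept)      0.12  -0.19 to 0.42 4.6e-01
#>                   age     -0.07  -0.29 to 0.15 5.4e-01
#>                gender     -0.24  -0.68 to 0.20 2.9e-01
#>            met_sum_1h      0.04  -0.02 to 0.10 2.2e-01
#>                  slot      0.02  -0.03 to 0.06 4.4e-01
#>  mean_sleep_hr_within     -0.13 -0.17 to -0.08 2.0e-08
#>      midpoint_between     -0.20  -0.42 to 0.02 7.8e-02
```

The within-person sleep heart-rate deviation comes back at −0.13 against a
generating slope of −0.12: nights with an elevated sleeping heart rate are
followed by lower energy. The between-person midpoint slope (−0.20,
generating value −0.26; attenuated because the person mean is estimated
from ~8 nights) says that habitually later sleepers report less energy
overall.

A complete run — five CSVs, feature tables, quartile comparison table, ICCs,
three model tables, and a Markdown/JSON report — is one call (or the
equivalent `inst/cli/emawear.R` subcommands):

```r
cmd_all(gen_config(seed = 1), "run_dir")
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline (simulate → features → analyze →
report) on a seeded cohort and writes the acceptance-target JSON. The
methods vignette (`vignettes/emawear-methods.Rmd`) documents the model, the
generator's ground-truth parameterization, numerical conventions, and known
limitations.
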