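# Synthetic cohort generator.
#
# Every simulate_* function derives its own RNG seed from config$seed (a
# fixed offset per stage), so each stage is individually reproducible and
# the full study is byte-identical for identical configs.

seed_for <- function(config, stage) {
  offsets <- c(cohort = 0L, nights = 1L, heart_rate = 2L, activity = 3L,
               ema = 4L, questionnaires = 5L)
  set.seed(config$seed + offsets[[stage]])
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

#' Generate participant traits
#'
#' Draws a gender-balanced cohort of latent person-level traits: age,
#' habitual bedtime (chronotype, minutes after noon), night-to-night bedtime
#' SD (regularity), a standard-normal latent stress trait, and the baseline
#' sleeping heart rate. Latent stress is positively coupled to both late
#' chronotype and irregularity, so generated questionnaire scores reproduce
#' the qualitative links the pipeline should detect (later bedtime and
#' larger midpoint variability go with higher stress / sleepiness scores).
#'
#' @param config a [gen_config()].
#' @return data.frame with one row per participant: `participant_id`, `age`,
#'   `gender` (0/1, balanced to within one), `chronotype`, `regularity_sd`,
#'   `latent_stress`, `base_sleep_hr`.
#' @export
generate_cohort <- function(config) {
  validate_gen_config(config)
  seed_for(config, "cohort")
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  gender <- rep_len(c(0L, 1L), n)          # balanced to within 1
  age <- round(rnorm_clip(n, 40.4, 11.8, 22, 65))
  z_chrono <- stats::rnorm(n)
  chronotype <- config$chronotype_mean + config$chronotype_sd * z_chrono
  rng <- config$regularity_sd_range
  u_reg <- stats::runif(n)
  regularity_sd <- rng[1] + (rng[2] - rng[1]) * u_reg
  z_reg <- stats::qnorm(pmin(pmax(u_reg, 1e-6), 1 - 1e-6))
  # stress loads on late chronotype and irregularity plus independent noise
  latent_stress <- 0.4 * z_chrono + 0.4 * z_reg + sqrt(1 - 0.32) * stats::rnorm(n)
  base_sleep_hr <- rnorm_clip(n, config$base_hr_mean, config$base_hr_sd, 40, 100)
  data.frame(participant_id = ids, age = age, gender = gender,
             chronotype = chronotype, regularity_sd = regularity_sd,
             latent_stress = latent_stress, base_sleep_hr = base_sleep_hr,
             stringsAsFactors = FALSE)
}

#' Generate per-night ground truth
#'
#' The hidden nightly state from which both the raw sleep records and the
#' 5-second pulse stream are derived. Night `i` starts on the evening of
#' study day `i` and ends on the morning of day `i + 1` (its `night_date`,
#' the wake-morning date, is the anchor used for EMA matching). Bedtime is
#' Normal(chronotype, regularity_sd); time in bed and sleep efficiency are
#' independent nightly draws; with probability `split_prob` the night is
#' exported as two disjoint in-bed records separated by a 30-60 minute gap
#' (time in bed stays the *union* length). `z_hr_night` is the standardized
#' per-night sleep heart-rate offset — the ground truth behind the
#' "deviation of heart rate during sleep" predictor.
#'
#' @inheritParams simulate_nights
#' @return data.frame, one row per participant-night.
#' @export
simulate_night_features <- function(traits, config) {
  validate_gen_config(config)
  seed_for(config, "nights")
  n_nights <- config$n_days
  grid <- expand.grid(night_index = seq_len(n_nights),
                      participant_id = traits$participant_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$night_index), ]
  m <- nrow(grid)
  tr <- traits[match(grid$participant_id, traits$participant_id), ]
  bedtime_min <- round(stats::rnorm(m, tr$chronotype, tr$regularity_sd))
  tib_min <- round(rnorm_clip(m, config$tib_mean, config$tib_sd, 240, 720))
  eff <- rnorm_clip(m, config$sleep_eff_mean, config$sleep_eff_sd, 0.70, 1.00)
  sleep_min <- pmin(round(tib_min * eff), tib_min)
  split <- stats::runif(m) < config$split_prob
  gap_min <- ifelse(split, round(stats::runif(m, 30, 60)), 0)
  gap_at <- ifelse(split, round(tib_min * stats::runif(m, 0.3, 0.7)), NA)
  z_hr_night <- stats::rnorm(m)
  span_min <- tib_min + gap_min
  evening_date <- config$start_date + grid$night_index - 1L
  data.frame(
    participant_id = grid$participant_id,
    night_index = grid$night_index,
    evening_date = evening_date,
    night_date = evening_date + 1L,
    bedtime_min = bedtime_min,
    tib_min = tib_min,
    sleep_min = sleep_min,
    midpoint_min = bedtime_min + span_min / 2,
    split = split, gap_min = gap_min, gap_at = gap_at,
    z_hr_night = z_hr_night,
    mean_sleep_hr = tr$base_sleep_hr + config$hr_night_sd * z_hr_night,
    stringsAsFactors = FALSE
  )
}

#' Simulate raw sleep records
#'
#' Emits the device-style in-bed record table (`participant_id`,
#' `bed_start`, `bed_end`, `minutes_asleep`). Split nights produce two
#' disjoint records whose asleep minutes are divided proportionally to
#' record length, so consolidation recovers the night truth exactly. The
#' nightly ground-truth table is attached as attribute `"truth"`.
#'
#' @param traits cohort from [generate_cohort()].
#' @param config a [gen_config()].
#' @return data.frame of raw sleep records (see [read_sleep()]).
#' @export
simulate_nights <- function(traits, config) {
  truth <- simulate_night_features(traits, config)
  start <- noon_of(truth$evening_date) + 60 * truth$bedtime_min
  recs <- vector("list", 2L)
  whole <- !truth$split
  recs[[1]] <- data.frame(
    participant_id = truth$participant_id,
    bed_start = start,
    bed_end = start + 60 * ifelse(whole, truth$tib_min, truth$gap_at),
    minutes_asleep = ifelse(whole, truth$sleep_min,
                            round(truth$sleep_min * truth$gap_at / truth$tib_min)),
    stringsAsFactors = FALSE
  )
  sp <- truth[truth$split, , drop = FALSE]
  if (nrow(sp)) {
    start2 <- noon_of(sp$evening_date) + 60 * (sp$bedtime_min + sp$gap_at + sp$gap_min)
    first_asleep <- round(sp$sleep_min * sp$gap_at / sp$tib_min)
    recs[[2]] <- data.frame(
      participant_id = sp$participant_id,
      bed_start = start2,
      bed_end = start2 + 60 * (sp$tib_min - sp$gap_at),
      minutes_asleep = sp$sleep_min - first_asleep,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  out <- out[order(out$participant_id, out$bed_start), ]
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

# In-bed intervals (including split structure) from the night truth table.
truth_intervals <- function(truth) {
  start <- noon_of(truth$evening_date) + 60 * truth$bedtime_min
  span <- truth$tib_min + truth$gap_min
  data.frame(participant_id = truth$participant_id,
             night_date = truth$night_date,
             int_start = start, int_end = start + 60 * span,
             mean_sleep_hr = truth$mean_sleep_hr,
             stringsAsFactors = FALSE)
}

#' Simulate the 5-second pulse-rate stream
#'
#' Generates pulse samples on a 5-second grid for each participant-day.
#' During a night's in-bed span the rate is centred on that night's true
#' sleeping heart rate (base rate plus the per-night offset); awake, it is
#' higher with a smooth diurnal pattern peaking mid-afternoon. Whole minutes
#' are dropped independently with probability `missing_wear_rate` to emulate
#' non-wear.
#'
#' Streams are large (17,280 samples per participant-day); pass `days` to
#' generate a subset lazily.
#'
#' @param traits cohort table.
#' @param night_truth nightly ground truth from [simulate_night_features()]
#'   (or the `"truth"` attribute of [simulate_nights()]).
#' @param config a [gen_config()].
#' @param days optional integer study-day indices to generate (default all
#'   `1:(n_days + 1)`; the extra morning covers the last wake).
#' @return data.frame `participant_id`, `timestamp`, `bpm`.
#' @export
simulate_heart_rate <- function(traits, night_truth, config, days = NULL) {
  validate_gen_config(config)
  seed_for(config, "heart_rate")
  if (is.null(days)) days <- seq_len(config$n_days + 1L)
  days <- sort(unique(as.integer(days)))
  ints <- data.table::as.data.table(truth_intervals(night_truth))
  day0 <- as.numeric(noon_of(config$start_date)) - 12 * 3600  # midnight day 1
  per_day <- 17280L
  out <- vector("list", length(days) * nrow(traits))
  k <- 0L
  for (pi in seq_len(nrow(traits))) {
    pid <- traits$participant_id[pi]
    base <- traits$base_sleep_hr[pi]
    pints <- ints[ints$participant_id == pid]
    data.table::setorder(pints, int_start)
    s0 <- as.numeric(pints$int_start); s1 <- as.numeric(pints$int_end)
    shr <- pints$mean_sleep_hr
    for (d in days) {
      t <- day0 + (d - 1L) * 86400 + 5 * (seq_len(per_day) - 1L)
      # map each sample to the in-bed interval containing it (if any)
      idx <- findInterval(t, s0)
      in_bed <- idx >= 1L & t < s1[pmax(idx, 1L)]
      hour <- (t - day0) %% 86400 / 3600
      wake_bpm <- base + config$wake_hr_offset +
        6 * sin(2 * pi * (hour - 9) / 24)
      bpm <- ifelse(in_bed, shr[pmax(idx, 1L)], wake_bpm) +
        stats::rnorm(per_day, 0, config$hr_sample_sd)
      keep <- rep(TRUE, per_day)
      if (config$missing_wear_rate > 0) {
        worn <- stats::runif(1440L) >= config$missing_wear_rate
        keep <- worn[(floor((t - day0) %% 86400 / 60)) + 1L]
      }
      k <- k + 1L
      out[[k]] <- data.frame(participant_id = pid,
                             timestamp = as.POSIXct(t[keep], origin = "1970-01-01",
                                                    tz = ema_tz),
                             bpm = round(pmin(pmax(bpm[keep], 30), 220), 1),
                             stringsAsFactors = FALSE)
    }
  }
  res <- data.table::rbindlist(out[seq_len(k)])
  data.table::setorder(res, participant_id, timestamp)
  as.data.frame(res)
}

#' Simulate minute-level activity (steps and METs)
#'
#' One row per worn participant-minute: steps are Poisson with a daytime
#' profile and zero in bed; METs are near-resting in bed and mildly active
#' awake. Minute missingness uses the same wear rate as the pulse stream
#' (drawn independently).
#'
#' @inheritParams simulate_heart_rate
#' @return data.frame `participant_id`, `minute_start`, `steps`, `mets`.
#' @export
simulate_activity <- function(traits, night_truth, config, days = NULL) {
  validate_gen_config(config)
  seed_for(config, "activity")
  if (is.null(days)) days <- seq_len(config$n_days + 1L)
  days <- sort(unique(as.integer(days)))
  ints <- truth_intervals(night_truth)
  day0 <- as.numeric(noon_of(config$start_date)) - 12 * 3600
  out <- vector("list", length(days) * nrow(traits))
  k <- 0L
  for (pi in seq_len(nrow(traits))) {
    pid <- traits$participant_id[pi]
    pints <- ints[ints$participant_id == pid, , drop = FALSE]
    pints <- pints[order(pints$int_start), , drop = FALSE]
    s0 <- as.numeric(pints$int_start); s1 <- as.numeric(pints$int_end)
    for (d in days) {
      t <- day0 + (d - 1L) * 86400 + 60 * (seq_len(1440L) - 1L)
      idx <- findInterval(t, s0)
      in_bed <- idx >= 1L & t < s1[pmax(idx, 1L)]
      hour <- (t - day0) %% 86400 / 3600
      awake_day <- !in_bed & hour >= 7 & hour <= 22
      lambda <- ifelse(in_bed, 0, ifelse(awake_day, 12, 1))
      steps <- stats::rpois(1440L, lambda)
      mets <- ifelse(in_bed, 0.9,
                     pmax(0.9, 1.2 + 0.04 * steps + stats::rnorm(1440L, 0, 0.2)))
      keep <- stats::runif(1440L) >= config$missing_wear_rate
      k <- k + 1L
      out[[k]] <- data.frame(
        participant_id = pid,
        minute_start = as.POSIXct(t[keep], origin = "1970-01-01", tz = ema_tz),
        steps = steps[keep], mets = round(mets[keep], 2),
        stringsAsFactors = FALSE)
    }
  }
  res <- data.table::rbindlist(out[seq_len(k)])
  data.table::setorder(res, participant_id, minute_start)
  as.data.frame(res)
}

#' Simulate EMA responses
#'
#' For each participant x EMA day x prompt, a latent standardized outcome is
#' generated from the known multilevel model
#' \deqn{y = \gamma' z + b_i + e_{it}}
#' where the z are the (population-standardized) within-person sleep
#' heart-rate deviation and time-in-bed deviation of the previous night and
#' the between-person chronotype (expected sleep midpoint), `b_i` is a
#' person intercept and `e` the occasion residual. Variance weights are
#' rescaled so the latent outcome has unit total variance, then mapped to
#' the recorded Visual Analog Scale as `round(50 + 20 y)` clipped to
#' [0, 100]. Energy loads on `gamma_within_hr` and `gamma_between_midpoint`,
#' sleepiness on `gamma_within_tib`, mood on neither (person intercept and
#' residual only).
#'
#' Response time is the scheduled time plus a lognormal latency (median 11.8
#' minutes by default), truncated to the slot's answer window; a fraction
#' `nonresponse_rate` of prompts is left unanswered (all fields missing).
#'
#' @param traits cohort table.
#' @param night_truth nightly ground truth (see [simulate_night_features()]).
#' @param config a [gen_config()].
#' @return data.frame in the `ema.csv` schema (see [read_ema()]), one row
#'   per scheduled prompt.
#' @export
simulate_ema <- function(traits, night_truth, config) {
  validate_gen_config(config)
  seed_for(config, "ema")
  slots <- config$prompt_times
  grid <- expand.grid(slot = seq_along(slots), ema_day = config$ema_days,
                      participant_id = traits$participant_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$ema_day, grid$slot), ]
  m <- nrow(grid)
  tr <- traits[match(grid$participant_id, traits$participant_id), ]

  # previous night for EMA day d = night whose wake morning is day d
  key_obs <- paste(grid$participant_id, grid$ema_day - 1L)
  key_night <- paste(night_truth$participant_id, night_truth$night_index)
  nt <- night_truth[match(key_obs, key_night), ]

  z_hr <- nt$z_hr_night
  z_tib <- (nt$tib_min - config$tib_mean) / config$tib_sd
  z_mid <- (tr$chronotype - config$chronotype_mean) / config$chronotype_sd

  n_pid <- nrow(traits)
  vtot <- config$var_intercept + config$var_residual
  latent_for <- function(gammas, zmat) {
    g2 <- sum(gammas^2)
    vi <- (1 - g2) * config$var_intercept / vtot
    vr <- (1 - g2) * config$var_residual / vtot
    b <- stats::rnorm(n_pid, 0, sqrt(vi))
    drop(zmat %*% gammas) + b[match(grid$participant_id, traits$participant_id)] +
      stats::rnorm(m, 0, sqrt(vr))
  }
  lat_energy <- latent_for(c(config$gamma_within_hr, config$gamma_between_midpoint),
                           cbind(z_hr, z_mid))
  lat_mood <- latent_for(numeric(0), matrix(0, m, 0))
  lat_sleepy <- latent_for(config$gamma_within_tib, cbind(z_tib))
  to_vas <- function(y) as.integer(pmin(100, pmax(0, round(50 + 20 * y))))

  sched <- clock_time_of(config$start_date + grid$ema_day - 1L, slots[grid$slot])
  slot_min <- prompt_minutes(slots)
  window_min <- c(diff(slot_min), 24 * 60 - 1 - slot_min[length(slot_min)])
  latency <- stats::rlnorm(m, config$latency_meanlog, config$latency_sdlog)
  latency <- pmin(latency, window_min[grid$slot] - 1)
  answered <- stats::runif(m) >= config$nonresponse_rate

  out <- data.frame(
    participant_id = grid$participant_id,
    study_day = config$start_date + grid$ema_day - 1L,
    scheduled_time = slots[grid$slot],
    response_time = sched + 60 * round(latency, 2),
    sleepiness = to_vas(lat_sleepy),
    mood = to_vas(lat_mood),
    energy = to_vas(lat_energy),
    stringsAsFactors = FALSE
  )
  out$response_time[!answered] <- NA
  out$sleepiness[!answered] <- NA_integer_
  out$mood[!answered] <- NA_integer_
  out$energy[!answered] <- NA_integer_
  rownames(out) <- NULL
  out
}

# Instrument score ranges (min, max).
instrument_ranges <- list(
  PSS = c(0, 40), SWLS = c(5, 35), `SPANE-P` = c(6, 30),
  `SPANE-N` = c(6, 30), `FS-J` = c(8, 56), JESS = c(0, 24)
)

#' Simulate stress and well-being questionnaire scores
#'
#' Scores at baseline and final are monotone functions of the latent stress
#' trait, chronotype, and each participant's realized mean weekly SD of the
#' sleep midpoint, plus Gaussian noise, rounded and clipped to each
#' instrument's range (PSS 0-40, SWLS 5-35, SPANE-P/N 6-30, FS-J 8-56,
#' JESS 0-24). Directions encode the associations the pipeline should
#' recover: later bedtime raises PSS/JESS and lowers SWLS; larger midpoint
#' variability raises PSS and lowers FS-J/SPANE-P.
#'
#' @inheritParams simulate_ema
#' @return data.frame `participant_id`, `instrument`, `timepoint`, `score`.
#' @export
simulate_questionnaires <- function(traits, night_truth, config) {
  validate_gen_config(config)
  seed_for(config, "questionnaires")
  n <- nrow(traits)
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n)

  nights <- data.frame(participant_id = night_truth$participant_id,
                       night_date = night_truth$night_date,
                       midpoint = night_truth$midpoint_min)
  wk <- weekly_regularity(nights, start_date = config$start_date + 1L)
  midsd <- tapply(wk$midpoint_sd_min, wk$participant_id, mean, na.rm = TRUE)
  midsd <- as.numeric(midsd[traits$participant_id])
  midsd[is.na(midsd)] <- mean(midsd, na.rm = TRUE)

  z_st <- zs(traits$latent_stress)
  z_ch <- zs(traits$chronotype)
  z_ms <- zs(midsd)
  s <- config$questionnaire_effect_scale
  lat <- list(
    PSS       = 19.2 + s * (3.0 * z_st + 1.5 * z_ch + 2.0 * z_ms),
    SWLS      = 22.1 - s * (2.5 * z_st + 1.5 * z_ch),
    `SPANE-P` = 20.7 - s * (2.0 * z_st + 2.0 * z_ms),
    `SPANE-N` = 16.9 + s * (2.5 * z_st + 1.5 * z_ch),
    `FS-J`    = 39.8 - s * (2.5 * z_st + 2.5 * z_ms),
    JESS      = 8.1  + s * (1.5 * z_st + 2.5 * z_ch)
  )
  out <- list()
  for (tp in c("baseline", "final")) {
    for (ins in names(lat)) {
      rng <- instrument_ranges[[ins]]
      score <- round(lat[[ins]] + stats::rnorm(n, 0, config$questionnaire_noise_sd))
      out[[paste(tp, ins)]] <- data.frame(
        participant_id = traits$participant_id, instrument = ins,
        timepoint = tp, score = as.integer(pmin(rng[2], pmax(rng[1], score))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$instrument, res$timepoint), ]
  rownames(res) <- NULL
  res
}

#' Simulate a complete study
#'
#' Orchestrates all generator stages and returns every table plus the
#' ground-truth parameterization used (for recovery tests).
#'
#' @param config a [gen_config()].
#' @param streams generate the 5-second pulse and minute-activity streams
#'   (large); if `FALSE` only night truth, sleep records, EMA and
#'   questionnaires are produced.
#' @param stream_days optional day subset forwarded to the stream
#'   generators.
#' @return list with `traits`, `night_truth`, `sleep_records`, `ema`,
#'   `questionnaires`, optionally `heart_rate` and `activity`, and
#'   `ground_truth` (generating parameters).
#' @export
simulate_study <- function(config = gen_config(), streams = TRUE,
                           stream_days = NULL) {
  validate_gen_config(config)
  traits <- generate_cohort(config)
  sleep_records <- simulate_nights(traits, config)
  truth <- attr(sleep_records, "truth")
  ema <- simulate_ema(traits, truth, config)
  questionnaires <- simulate_questionnaires(traits, truth, config)
  out <- list(traits = traits, night_truth = truth,
              sleep_records = sleep_records, ema = ema,
              questionnaires = questionnaires,
              ground_truth = list(
                gamma_within_hr = config$gamma_within_hr,
                gamma_between_midpoint = config$gamma_between_midpoint,
                gamma_within_tib = config$gamma_within_tib,
                var_intercept = config$var_intercept,
                var_residual = config$var_residual,
                icc_null = config$var_intercept /
                  (config$var_intercept + config$var_residual),
                seed = config$seed))
  if (isTRUE(streams)) {
    out$heart_rate <- simulate_heart_rate(traits, truth, config, days = stream_days)
    out$activity <- simulate_activity(traits, truth, config, days = stream_days)
  }
  out
}

#' Night-level cardiac ground truth in the NightCardiac schema
#'
#' Maps the generator's nightly truth to the schema produced by
#' [segment_and_summarize()], for use where regenerating the full 5-second
#' stream is not needed (the per-night mean sleeping heart rate is exact and
#' the window SDNN is not defined without samples, so `sleep_sdnn_ms` is
#' `NA`).
#'
#' @param night_truth from [simulate_night_features()].
#' @return data.frame `participant_id`, `night_date`, `mean_sleep_hr`,
#'   `sleep_sdnn_ms`, `n_windows`.
#' @export
truth_night_cardiac <- function(night_truth) {
  data.frame(participant_id = night_truth$participant_id,
             night_date = night_truth$night_date,
             mean_sleep_hr = night_truth$mean_sleep_hr,
             sleep_sdnn_ms = NA_real_,
             n_windows = NA_integer_,
             stringsAsFactors = FALSE)
}
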