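test_that("prior-hour aggregation uses the half-open window before response", {
  rt <- ts_("2022-02-01 12:30:00")
  act <- data.frame(participant_id = "P1",
                    minute_start = minutes_seq("2022-02-01 11:00:00", 120),
                    steps = 1L, mets = 1.0)
  agg <- match_prior_activity(rt, act)
  expect_equal(agg$met_sum_1h, 60)   # exactly [11:30, 12:30)
  expect_equal(agg$steps_1h, 60)

  # the response minute itself is excluded
  act2 <- act[act$minute_start == ts_("2022-02-01 12:30:00"), ]
  expect_true(is.na(match_prior_activity(rt, act2)$met_sum_1h))

  empty <- act[0, ]
  expect_true(is.na(match_prior_activity(rt, empty)$met_sum_1h))

  hr <- hr_at_minutes(minutes_seq("2022-02-01 11:30:00", 60), bpm = 80)
  expect_equal(match_prior_activity(rt, act, hr)$mean_hr_1h, 80)
})

test_that("previous-night matching uses the 18:00-09:00 window", {
  nights <- rbind(
    consolidate_night(sleep_rec("2022-02-01 23:00:00", "2022-02-02 08:50:00", 500)),
    consolidate_night(sleep_rec("2022-02-02 23:30:00", "2022-02-03 09:30:00", 500)))
  hit <- match_previous_sleep(as.Date("2022-02-02"), nights)
  expect_equal(hit$night_date, as.Date("2022-02-02"))  # wake 08:50 matched
  # wake 09:30 falls outside the window for its own morning
  expect_null(match_previous_sleep(as.Date("2022-02-03"), nights))

  # two raw records in one window yield a single consolidated match
  recs <- rbind(sleep_rec("2022-02-01 22:30:00", "2022-02-02 01:00:00", 130),
                sleep_rec("2022-02-02 02:00:00", "2022-02-02 06:30:00", 250))
  cn <- consolidate_nights(recs)
  m <- match_previous_sleep(as.Date("2022-02-02"), cn)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_records, 2)
})

test_that("observation table keeps same-day answered prompts with features", {
  cfg <- gen_config(n_participants = 3, n_days = 6, nonresponse_rate = 0,
                    missing_wear_rate = 0, split_prob = 0, seed = 15)
  study <- simulate_study(cfg, streams = FALSE)
  nights <- consolidate_nights(study$sleep_records)
  obs <- build_observation_table(study$ema, NULL, NULL, nights,
                                 truth_night_cardiac(study$night_truth),
                                 study$traits[, c("participant_id", "age", "gender")])
  # zero missingness: one row per prompt
  expect_equal(nrow(obs), 3 * length(cfg$ema_days) * 4)
  # nearly every prompt has a previous night (a late waker past 09:00 may not)
  expect_gt(mean(!is.na(obs$bedtime)), 0.7)
  expect_true(all(!is.na(obs$age)))
  # no observation references a night waking after the response
  night_wake <- nights$wake_time[match(paste(obs$participant_id, obs$night_date),
                                       paste(nights$participant_id, nights$night_date))]
  expect_true(all(night_wake <= obs$response_time, na.rm = TRUE))

  # a prompt answered after midnight is excluded
  ema2 <- study$ema
  ema2$response_time[1] <- ema2$response_time[1] + 24 * 3600
  obs2 <- build_observation_table(ema2, NULL, NULL, nights, NULL, NULL)
  expect_equal(nrow(obs2), nrow(obs) - 1)

  # construction is order-independent
  ema3 <- study$ema[rev(seq_len(nrow(study$ema))), ]
  obs3 <- build_observation_table(ema3, NULL, NULL, nights,
                                  truth_night_cardiac(study$night_truth),
                                  study$traits[, c("participant_id", "age", "gender")])
  expect_equal(obs3, obs)
})

test_that("wear filters blank the matching feature sets", {
  ema <- ema_table("P1", days = 2)[2, ]   # one noon prompt on day 2
  nights <- consolidate_nights(
    sleep_rec("2022-02-01 23:00:00", "2022-02-02 07:00:00", 420))
  # full overnight wear but only 30 worn minutes in the prior hour
  hr_night <- hr_at_minutes(minutes_seq("2022-02-01 18:00:00", 900), bpm = 60)
  hr_pre <- hr_at_minutes(minutes_seq("2022-02-02 11:10:00", 30), bpm = 80)
  hr <- rbind(hr_night, hr_pre)
  act <- data.frame(participant_id = "P1",
                    minute_start = minutes_seq("2022-02-02 11:10:00", 30),
                    steps = 0L, mets = 1.0)
  obs <- build_observation_table(ema, act, hr, nights, NULL, NULL)
  expect_false(obs$pre_ema_ok)
  expect_true(obs$overnight_ok)
  expect_true(is.na(obs$met_sum_1h))   # concurrent aggregates blanked
  expect_false(is.na(obs$bedtime))     # sleep features kept

  # flags only, no blanking
  obs_flag <- build_observation_table(ema, act, hr, nights, NULL, NULL,
                                      apply_filters = FALSE)
  expect_equal(obs_flag$met_sum_1h, 30)
  # row-dropping mode
  obs_drop <- build_observation_table(ema, act, hr, nights, NULL, NULL,
                                      apply_filters = "drop")
  expect_equal(nrow(obs_drop), 0)
})
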