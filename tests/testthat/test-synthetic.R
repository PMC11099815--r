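test_that("cohort generation is deterministic, balanced, and bounded", {
  cfg <- gen_config(n_participants = 40, n_days = 14, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$gender == 0), 20)   # 1:1 male-to-female cohort
  expect_equal(sum(a$gender == 1), 20)
  expect_true(all(a$base_sleep_hr >= 40 & a$base_sleep_hr <= 100))
  expect_true(all(a$regularity_sd > 0))
  # odd cohort balanced to within one
  odd <- generate_cohort(gen_config(n_participants = 7, seed = 3))
  expect_lte(abs(sum(odd$gender == 0) - sum(odd$gender == 1)), 1)
  # degenerate regularity range pins the trait
  deg <- generate_cohort(gen_config(n_participants = 2,
                                    regularity_sd_range = c(30, 30), seed = 1))
  expect_equal(deg$regularity_sd, c(30, 30))
})

test_that("nightly records follow the configured bedtime process", {
  # zero-noise limit: one record per night at (rounded) chronotype
  cfg0 <- gen_config(n_participants = 2, n_days = 5,
                     regularity_sd_range = c(1e-6, 1e-6), split_prob = 0, seed = 2)
  tr <- generate_cohort(cfg0)
  recs <- simulate_nights(tr, cfg0)
  expect_equal(nrow(recs), 2 * 5)
  truth <- attr(recs, "truth")
  expect_true(all(abs(truth$bedtime_min - tr$chronotype[
    match(truth$participant_id, tr$participant_id)]) <= 0.5))
  expect_true(all(truth$sleep_min <= truth$tib_min))

  # forced splitting: every night yields two disjoint records
  cfg1 <- gen_config(n_participants = 2, n_days = 4, split_prob = 1, seed = 2)
  recs1 <- simulate_nights(generate_cohort(cfg1), cfg1)
  expect_equal(nrow(recs1), 2 * 4 * 2)
  nights <- consolidate_nights(recs1)
  expect_true(all(nights$n_records == 2))
  expect_true(all(nights$sleep_min <= nights$tib_min))

  # Monte-Carlo: realized bedtime SD tracks the generating regularity_sd
  cfg2 <- gen_config(n_participants = 2, n_days = 200,
                     regularity_sd_range = c(40, 40), split_prob = 0, seed = 5)
  truth2 <- simulate_night_features(generate_cohort(cfg2), cfg2)
  sds <- tapply(truth2$bedtime_min, truth2$participant_id, sd)
  expect_true(all(abs(sds - 40) / 40 < 0.10))
})

test_that("pulse stream honours wear gaps and nightly rate structure", {
  cfg <- gen_config(n_participants = 2, n_days = 2, missing_wear_rate = 0,
                    seed = 4)
  tr <- generate_cohort(cfg)
  truth <- simulate_night_features(tr, cfg)
  hr <- simulate_heart_rate(tr, truth, cfg, days = 1)
  p1 <- hr[hr$participant_id == "P001", ]
  cov <- minute_coverage(p1, "2022-02-01 00:00:00", "2022-02-02 00:00:00")
  expect_equal(cov$coverage, 1.0)

  cfg25 <- gen_config(n_participants = 2, n_days = 2, missing_wear_rate = 0.25,
                      seed = 4)
  hr25 <- simulate_heart_rate(tr, truth, cfg25, days = 1)
  cov25 <- minute_coverage(hr25[hr25$participant_id == "P001", ],
                           "2022-02-01 00:00:00", "2022-02-02 00:00:00")
  expect_lt(abs(cov25$coverage - 0.75), 0.05)

  # all noise zeroed: constant rate in bed implies SDNN 0 downstream
  cfg0 <- gen_config(n_participants = 2, n_days = 2, missing_wear_rate = 0,
                     hr_night_sd = 0, hr_sample_sd = 0, split_prob = 0, seed = 4)
  tr0 <- generate_cohort(cfg0)
  truth0 <- simulate_night_features(tr0, cfg0)
  recs0 <- simulate_nights(tr0, cfg0)
  hr0 <- simulate_heart_rate(tr0, truth0, cfg0, days = c(1, 2))
  seg <- segment_and_summarize(hr0, consolidate_nights(recs0))
  sl <- seg$windows[seg$windows$context == "sleep" & !is.na(seg$windows$sdnn_ms), ]
  expect_gt(nrow(sl), 0)
  # interior sleep windows (boundary windows mix wake and sleep rates)
  interior <- do.call(rbind, lapply(
    split(sl, list(sl$participant_id, sl$night_date), drop = TRUE),
    function(g) g[g$window_start > min(g$window_start) &
                    g$window_start < max(g$window_start), ]))
  expect_gt(nrow(interior), 0)
  expect_true(all(interior$sdnn_ms < 1e-9))
})

test_that("EMA responses reproduce nonresponse, clipping and variance structure", {
  # response rate calibrated to the nonresponse fraction
  cfg <- gen_config(n_participants = 40, n_days = 14, nonresponse_rate = 0.1266,
                    seed = 6)
  tr <- generate_cohort(cfg)
  truth <- simulate_night_features(tr, cfg)
  answered <- total <- 0
  for (s in 1:5) {
    cfg$seed <- 6L + s
    e <- simulate_ema(tr, truth, cfg)
    answered <- answered + sum(!is.na(e$response_time))
    total <- total + nrow(e)
  }
  expect_lt(abs(100 * answered / total - 87.34), 1.5)

  # all prompts answered and VAS in range; response after schedule, same day
  cfg0 <- gen_config(n_participants = 4, n_days = 14, nonresponse_rate = 0, seed = 7)
  tr0 <- generate_cohort(cfg0)
  e0 <- simulate_ema(tr0, simulate_night_features(tr0, cfg0), cfg0)
  expect_equal(nrow(e0), 4 * length(cfg0$ema_days) * 4)
  expect_true(all(!is.na(e0$response_time)))
  sched <- as.POSIXct(paste(e0$study_day, paste0(e0$scheduled_time, ":00")), tz = tz_)
  expect_true(all(e0$response_time >= sched))
  expect_true(all(as.Date(e0$response_time, tz = tz_) == e0$study_day))
  for (v in c("sleepiness", "mood", "energy"))
    expect_true(all(e0[[v]] >= 0 & e0[[v]] <= 100))

  # latent ICC approx var_i / (var_i + var_r) when slopes are zero
  iccs <- sapply(1:5, function(s) {
    cfgi <- gen_config(n_participants = 40, n_days = 14, gamma_within_hr = 0,
                       gamma_between_midpoint = 0, gamma_within_tib = 0,
                       var_intercept = 1, var_residual = 1, seed = 20 + s)
    tri <- generate_cohort(cfgi)
    ei <- simulate_ema(tri, simulate_night_features(tri, cfgi), cfgi)
    icc_unconditional(ei[!is.na(ei$response_time), ], "mood")$icc
  })
  expect_lt(abs(mean(iccs) - 0.5), 0.07)
})

test_that("VAS mapping clips at the scale boundaries", {
  # extreme slopes push latents far below 0 for late-midpoint participants
  cfg <- gen_config(n_participants = 30, n_days = 7,
                    gamma_between_midpoint = -0.9, var_intercept = 0.005,
                    var_residual = 0.005, nonresponse_rate = 0, seed = 11)
  tr <- generate_cohort(cfg)
  e <- simulate_ema(tr, simulate_night_features(tr, cfg), cfg)
  expect_true(any(e$energy == 0) || any(e$energy == 100))
  expect_true(all(e$energy >= 0 & e$energy <= 100))
})

test_that("questionnaire scores are monotone in traits and stay in range", {
  cfg <- gen_config(n_participants = 2, n_days = 14,
                    questionnaire_noise_sd = 0, seed = 8)
  # two participants identical except chronotype; same realized nights
  traits <- data.frame(participant_id = c("P001", "P002"), age = c(40, 40),
                       gender = c(0L, 1L), chronotype = c(650, 760),
                       regularity_sd = c(40, 40), latent_stress = c(0, 0),
                       base_sleep_hr = c(60, 60))
  nights <- data.frame(
    participant_id = rep(c("P001", "P002"), each = 14),
    night_date = rep(as.Date("2022-02-02") + 0:13, 2),
    midpoint_min = rep(900 + c(-20, 0, 20, 5, -5, 10, -10, 15, -15, 0, 8, -8, 3, -3), 2))
  qs <- simulate_questionnaires(traits, nights, cfg)
  base <- qs[qs$timepoint == "baseline", ]
  pss <- base$score[base$instrument == "PSS"]
  jess <- base$score[base$instrument == "JESS"]
  swls <- base$score[base$instrument == "SWLS"]
  expect_gte(pss[2], pss[1])    # later chronotype, higher stress score
  expect_gte(jess[2], jess[1])
  expect_lte(swls[2], swls[1])

  # ranges hold for arbitrary seeds
  for (s in c(1, 99)) {
    cfgs <- gen_config(n_participants = 12, n_days = 14, seed = s)
    trs <- generate_cohort(cfgs)
    q <- simulate_questionnaires(trs, simulate_night_features(trs, cfgs), cfgs)
    for (ins in unique(q$instrument)) {
      rng <- list(PSS = c(0, 40), SWLS = c(5, 35), `SPANE-P` = c(6, 30),
                  `SPANE-N` = c(6, 30), `FS-J` = c(8, 56), JESS = c(0, 24))[[ins]]
      sc <- q$score[q$instrument == ins]
      expect_true(all(sc >= rng[1] & sc <= rng[2]))
    }
  }
})

test_that("midpoint irregularity raises stress scores across a large cohort", {
  cfg <- gen_config(n_participants = 200, n_days = 14, seed = 9)
  tr <- generate_cohort(cfg)
  truth <- simulate_night_features(tr, cfg)
  qs <- simulate_questionnaires(tr, truth, cfg)
  nights <- data.frame(participant_id = truth$participant_id,
                       night_date = truth$night_date,
                       midpoint = truth$midpoint_min)
  wk <- weekly_regularity(nights)
  midsd <- tapply(wk$midpoint_sd_min, wk$participant_id, mean, na.rm = TRUE)
  pss <- qs$score[qs$instrument == "PSS" & qs$timepoint == "baseline"]
  names(pss) <- qs$participant_id[qs$instrument == "PSS" & qs$timepoint == "baseline"]
  rho <- cor(midsd[names(pss)], pss, method = "spearman")
  expect_gt(rho, 0)
})

test_that("the full simulated study is byte-identical given the seed", {
  cfg <- gen_config(n_participants = 3, n_days = 6, seed = 42)
  a <- simulate_study(cfg, streams = TRUE, stream_days = 2)
  b <- simulate_study(cfg, streams = TRUE, stream_days = 2)
  for (tb in c("traits", "night_truth", "sleep_records", "ema",
               "questionnaires", "heart_rate", "activity"))
    expect_identical(a[[tb]], b[[tb]])
})
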