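test_that("quartile split uses interpolated quantiles with inclusive bounds", {
  qs <- data.frame(participant_id = sprintf("P%d", 1:8), instrument = "PSS",
                   timepoint = "baseline", score = 1:8)
  sp <- quartile_split(qs, "PSS")
  expect_equal(sp$q1, 2.75)
  expect_equal(sp$q3, 6.25)
  expect_setequal(sp$low_ids, c("P1", "P2"))
  expect_setequal(sp$high_ids, c("P7", "P8"))
  expect_length(intersect(sp$low_ids, sp$high_ids), 0)

  sym <- qs; sym$score <- c(1, 2, 3, 4, 4, 3, 2, 1)
  sp2 <- quartile_split(sym, "PSS")
  expect_equal(length(sp2$low_ids), length(sp2$high_ids))

  degen <- qs; degen$score <- 7
  expect_error(quartile_split(degen, "PSS"), "degenerate")
  expect_error(quartile_split(qs[1:3, ], "PSS"), "at least 4")
})

test_that("Mann-Whitney separation case and degenerate inputs", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)          # 2 / choose(6, 3) by full enumeration
  expect_equal(mw$method, "exact enumeration")

  same <- mann_whitney(c(1, 2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney agrees with wilcox.test on both branches", {
  set.seed(4)
  for (i in 1:40) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- runif(n1); y <- runif(n2)
    mw <- mann_whitney(x, y)
    if (n1 + n2 <= 12) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
    }
    refn <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$p_normal, refn$p.value, tolerance = 1e-10)
    expect_equal(mw$u, unname(suppressWarnings(wilcox.test(x, y))$statistic))
  }
  # tied data exercise the tie-corrected variance
  for (i in 1:20) {
    x <- sample(1:4, 10, replace = TRUE); y <- sample(2:5, 12, replace = TRUE)
    mw <- mann_whitney(x, y)
    refn <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$p, refn$p.value, tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact enumeration where defined", {
  # enumerated bound: <= 0.02 when both groups have >= 4 and n1+n2 >= 11;
  # <= 0.09 for any group sizes >= 2 (the 2x2 worst case is 0.088)
  set.seed(5)
  worst_small <- worst_all <- 0
  for (i in 1:150) {
    n1 <- sample(2:9, 1); n2 <- sample(2:(12 - max(n1, 2)), 1)
    x <- runif(n1); y <- runif(n2)
    mw <- mann_whitney(x, y)
    d <- abs(mw$p_normal - mw$p)
    worst_all <- max(worst_all, d)
    if (min(n1, n2) >= 4 && n1 + n2 >= 11) worst_small <- max(worst_small, d)
  }
  expect_lte(worst_small, 0.02)
  expect_lte(worst_all, 0.09)
})

test_that("effect sizes and Bonferroni behave as defined", {
  expect_equal(effect_size_r(2, 100), 0.2)
  expect_equal(effect_size_r(0, 50), 0)
  expect_error(effect_size_r(1, 0), "positive")

  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(hedges_g(c(0, 0), c(1, 1)), "pooled SD")
  set.seed(6)
  g <- hedges_g(rnorm(2000, 0.5), rnorm(2000, 0))
  expect_lt(abs(g - 0.5), 0.1)

  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1.0)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.1, 0), "m")
  # monotone in p and m
  expect_lte(bonferroni(0.01, 3), bonferroni(0.02, 3))
  expect_lte(bonferroni(0.01, 3), bonferroni(0.01, 4))
})

test_that("|r| stays below 1 and label swap flips signed statistics", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    mw <- mann_whitney(x, y)
    r <- effect_size_r(mw$z, length(x) + length(y))
    expect_lte(abs(r), 1)
    sw <- mann_whitney(y, x)
    expect_equal(sw$z, -mw$z, tolerance = 1e-12)
    expect_equal(sw$p, mw$p, tolerance = 1e-12)
    if (sd(c(x, y)) > 0)
      expect_equal(hedges_g(y, x), -hedges_g(x, y), tolerance = 1e-12)
  }
})

test_that("quartile analysis detects the built-in chronotype-stress link", {
  cfg <- gen_config(n_participants = 24, n_days = 14, seed = 16)
  tr <- generate_cohort(cfg)
  truth <- simulate_night_features(tr, cfg)
  nights <- data.frame(participant_id = truth$participant_id,
                       night_date = truth$night_date,
                       bedtime = truth$bedtime_min, midpoint = truth$midpoint_min,
                       tib_min = truth$tib_min, sleep_min = truth$sleep_min,
                       efficiency_pct = 100 * truth$sleep_min / truth$tib_min)
  weekly <- weekly_regularity(nights)
  qn <- simulate_questionnaires(tr, truth, cfg)
  cmp <- suppressWarnings(run_quartile_analysis(
    nights, weekly, NULL, NULL, qn,
    metrics = c("bedtime", "midpoint", "tib_min", "sleep_min",
                "efficiency_pct", "midpoint_sd_min")))
  # generator builds in: later chronotype => higher PSS
  bed <- cmp[cmp$instrument == "PSS" & cmp$metric == "bedtime", ]
  expect_lt(bed$median_low, bed$median_high)
  # bookkeeping: family size equals metrics actually compared per instrument
  expect_true(all(cmp$m == 6))
  expect_equal(cmp$p_adjusted, pmin(1, cmp$p_raw * cmp$m))
})

test_that("participant-level unit controls the type-I error on null cohorts", {
  sig <- 0L; total <- 0L
  for (s in 1:40) {
    cfg <- gen_config(n_participants = 20, n_days = 14,
                      gamma_within_hr = 0, gamma_between_midpoint = 0,
                      gamma_within_tib = 0, questionnaire_effect_scale = 0,
                      seed = 300 + s)
    tr <- generate_cohort(cfg)
    truth <- simulate_night_features(tr, cfg)
    nights <- data.frame(participant_id = truth$participant_id,
                         night_date = truth$night_date,
                         bedtime = truth$bedtime_min, midpoint = truth$midpoint_min,
                         tib_min = truth$tib_min, sleep_min = truth$sleep_min,
                         efficiency_pct = 100 * truth$sleep_min / truth$tib_min)
    weekly <- weekly_regularity(nights)
    qn <- simulate_questionnaires(tr, truth, cfg)
    cmp <- suppressWarnings(run_quartile_analysis(
      nights, weekly, NULL, NULL, qn, unit = "participant",
      metrics = c("bedtime", "midpoint", "tib_min", "sleep_min",
                  "efficiency_pct", "midpoint_sd_min")))
    sig <- sig + sum(cmp$p_adjusted < 0.05)
    total <- total + nrow(cmp)
  }
  frac <- sig / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(frac, 0.05 + 2 * se)
})
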