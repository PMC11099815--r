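test_that("person-mean decomposition splits between and within components", {
  obs <- data.frame(participant_id = rep("P1", 3), x = c(700, 720, 740))
  d <- decompose(obs, "x")
  expect_equal(d$x_between, rep(720, 3))
  expect_equal(d$x_within, c(-20, 0, 20))

  const <- data.frame(participant_id = rep(c("A", "B"), each = 4),
                      x = rep(c(5, 9), each = 4))
  dc <- decompose(const, "x")
  expect_true(all(dc$x_within == 0))

  set.seed(8)
  rnd <- data.frame(participant_id = rep(sprintf("P%d", 1:10), each = 12),
                    x = rnorm(120))
  rnd$x[sample(120, 10)] <- NA
  dr <- decompose(rnd, "x")
  sums <- tapply(dr$x_within, dr$participant_id, sum, na.rm = TRUE)
  expect_true(all(abs(sums) < 1e-9))
  # reconstruction: between + within = original wherever nonmissing
  ok <- !is.na(rnd$x)
  expect_equal(dr$x_between[ok] + dr$x_within[ok], rnd$x[ok])
  expect_error(decompose(rnd, "nope"), "no such predictor")
})

test_that("standardization yields mean 0 and SD 1", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(4, 5)), "constant")
})

test_that("unconditional ICC recovers the generating variance ratio", {
  # zero between-person variance
  set.seed(9)
  obs0 <- data.frame(participant_id = rep(sprintf("P%02d", 1:30), each = 30),
                     y = rnorm(900))
  expect_lt(icc_unconditional(obs0, "y")$icc, 0.05)

  # equal variance components
  b <- rnorm(30)
  obs1 <- data.frame(participant_id = rep(sprintf("P%02d", 1:30), each = 30),
                     y = rep(b, each = 30) + rnorm(900))
  expect_lt(abs(icc_unconditional(obs1, "y")$icc - 0.5), 0.1)
  expect_error(icc_unconditional(obs0[obs0$participant_id == "P01", ], "y"),
               ">= 2 participants")
})

test_that("mixed-model fits report estimates, CIs and variance components", {
  set.seed(10)
  n_p <- 30; n_o <- 20
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:n_p), each = n_o),
                  x = rnorm(n_p * n_o))
  b <- rnorm(n_p, 0, 0.7)
  d$y <- 0.4 * d$x + rep(b, each = n_o) + rnorm(n_p * n_o)
  fit <- fit_mixed(d, "y", "x")
  est <- fit$fixed_effects[fit$fixed_effects$term == "x", ]
  expect_lt(abs(est$estimate - 0.4), 0.1)
  expect_true(est$ci_low < est$estimate && est$estimate < est$ci_high)
  expect_gt(fit$var_intercept, 0.2)
  expect_true(fit$converged)

  # duplicating every observation leaves the point estimates essentially
  # unchanged (cluster sizes double, so shrinkage weights move slightly)
  fit2 <- fit_mixed(rbind(d, d), "y", "x")
  est2 <- fit2$fixed_effects[fit2$fixed_effects$term == "x", ]
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-2)

  expect_error(fit_mixed(d, "y", "missing_term"), "missing column")
})

test_that("forward stepwise selection is greedy on AIC and deterministic", {
  set.seed(11)
  n_p <- 25; n_o <- 16
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:n_p), each = n_o),
                  ctrl = rnorm(n_p * n_o), strong = rnorm(n_p * n_o),
                  null1 = rnorm(n_p * n_o), null2 = rnorm(n_p * n_o))
  d$y <- 0.2 * d$ctrl + 0.6 * d$strong +
    rep(rnorm(n_p, 0, 0.5), each = n_o) + rnorm(n_p * n_o)

  one <- forward_stepwise(d, "y", "ctrl", "strong")
  expect_equal(one$selected, "strong")
  expect_equal(nrow(one$trace), 2)

  both <- forward_stepwise(d, "y", "ctrl", c("strong", "null1", "null2"))
  expect_true("strong" %in% both$selected)
  # AIC of the selected model never exceeds the controls-only model
  expect_lte(both$fit$aic, both$trace$aic[1])
  # AIC decreases monotonically along the trace
  expect_true(all(diff(both$trace$aic) < 0))

  again <- forward_stepwise(d, "y", "ctrl", c("strong", "null1", "null2"))
  expect_identical(both$trace, again$trace)

  # all-null candidates: controls-only model kept (this seed)
  d$y0 <- rep(rnorm(n_p, 0, 0.5), each = n_o) + rnorm(n_p * n_o)
  nullsel <- forward_stepwise(d, "y0", "ctrl", c("null1", "null2"))
  expect_length(nullsel$selected, 0)

  expect_error(forward_stepwise(d, "y", "ctrl", c("ctrl", "null1")), "disjoint")
})

test_that("null predictors are covered by their CIs at roughly nominal rate", {
  set.seed(12)
  cover <- logical(30)
  for (i in 1:30) {
    n_p <- 20; n_o <- 10
    d <- data.frame(participant_id = rep(sprintf("P%02d", 1:n_p), each = n_o),
                    x = rnorm(n_p * n_o))
    d$y <- rep(rnorm(n_p, 0, 0.6), each = n_o) + rnorm(n_p * n_o)
    fe <- fit_mixed(d, "y", "x")$fixed_effects
    est <- fe[fe$term == "x", ]
    cover[i] <- est$ci_low <= 0 && 0 <= est$ci_high
  }
  expect_gte(mean(cover), 0.8)   # ~95% nominal, binomial noise at n = 30
})

test_that("table models run on linked observations and format like the tables", {
  cfg <- gen_config(n_participants = 10, n_days = 14, nonresponse_rate = 0,
                    seed = 17)
  study <- simulate_study(cfg, streams = FALSE)
  nights <- consolidate_nights(study$sleep_records)
  obs <- build_observation_table(study$ema, NULL, NULL, nights,
                                 truth_night_cardiac(study$night_truth),
                                 study$traits[, c("participant_id", "age", "gender")])
  models <- build_table_models(obs, stepwise = FALSE)
  expect_named(models, c("energy", "mood", "sleepiness"))
  for (oc in names(models)) {
    fe <- models[[oc]]$fit$fixed_effects
    expect_true(all(c("term", "estimate", "ci_low", "ci_high", "p") %in% names(fe)))
    expect_true(all(fe$ci_low <= fe$estimate & fe$estimate <= fe$ci_high))
    expect_gte(models[[oc]]$fit$var_residual, 0)
    expect_output(print(models[[oc]]$fit), "Linear mixed model")
  }
})
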