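#' Synthetic-cohort generator configuration
#'
#' Builds and validates the configuration that drives every `simulate_*`
#' function. Defaults encode the study design the package emulates: a
#' 40-person office-worker cohort wearing a wrist device for 8 weeks, with
#' EMA prompts at 09:00, 12:00, 15:00 and 18:00 on 8 designated days, and
#' momentary outcomes generated from a known multilevel model whose
#' standardized slopes default to the headline estimates the pipeline is
#' meant to recover (within-person sleep heart-rate deviation on energy
#' -0.12, between-person sleep midpoint on energy -0.26, within-person time
#' in bed on sleepiness -0.10).
#'
#' The test-scale default is 8 participants x 14 days to keep runs fast;
#' `paper_scale = TRUE` switches to 40 x 56 with EMA days in weeks 1-2 and
#' 7-8.
#'
#' `var_intercept` and `var_residual` are treated as a *ratio*: the latent
#' outcome is rescaled so its total variance is 1, which keeps the
#' generating slopes on the standardized scale the mixed models estimate
#' and makes the unconditional intraclass correlation equal to
#' `var_intercept / (var_intercept + var_residual)` when all slopes are 0.
#'
#' @param n_participants number of participants (>= 2; gender balanced).
#' @param n_days number of study nights per participant.
#' @param ema_days integer study-day indices (>= 2) on which EMA prompts are
#'   sent; `NULL` picks 8 days (weeks 1-2 and 7-8 when the span allows,
#'   otherwise spread evenly).
#' @param prompt_times "HH:MM" prompt clock times, strictly increasing.
#' @param gamma_within_hr standardized slope of the within-person deviation
#'   of sleep heart rate on energy.
#' @param gamma_between_midpoint standardized slope of the person-mean sleep
#'   midpoint on energy.
#' @param gamma_within_tib standardized slope of the within-person deviation
#'   of time in bed on sleepiness.
#' @param var_intercept,var_residual between-person and occasion variance
#'   weights of the latent EMA outcomes (ratio; see Details).
#' @param chronotype_mean,chronotype_sd habitual bedtime distribution in
#'   minutes after noon (690 = 23:30).
#' @param regularity_sd_range range (min, max) of the per-person
#'   night-to-night bedtime SD, minutes.
#' @param tib_mean,tib_sd nightly time-in-bed distribution, minutes.
#' @param sleep_eff_mean,sleep_eff_sd nightly sleep-efficiency distribution
#'   (proportion scale).
#' @param base_hr_mean,base_hr_sd distribution of the person-level sleeping
#'   heart rate, bpm.
#' @param hr_night_sd within-person SD of the per-night sleep heart-rate
#'   offset, bpm (the ground truth behind the "deviation of heart rate
#'   during sleep" predictor).
#' @param hr_sample_sd 5-second pulse-sample measurement noise, bpm.
#' @param wake_hr_offset mean waking minus sleeping heart rate, bpm.
#' @param split_prob probability that a night is exported as two disjoint
#'   in-bed records (exercises consolidation).
#' @param missing_wear_rate fraction of minutes with no device data.
#' @param nonresponse_rate fraction of EMA prompts left unanswered
#'   (default 0.1266, calibrated to an 87.34% response rate).
#' @param latency_meanlog,latency_sdlog lognormal response-latency
#'   parameters, minutes (median 11.8 by default).
#' @param questionnaire_noise_sd SD of questionnaire measurement noise.
#' @param questionnaire_effect_scale multiplier on all questionnaire-trait
#'   couplings; 0 gives a zero-association (null) world.
#' @param start_date first study date.
#' @param paper_scale if TRUE, use the 40-participant x 56-day design.
#' @param seed integer RNG seed (< 2^31 - 16).
#' @return a validated list of class `"ema_gen_config"`.
#' @export
gen_config <- function(n_participants = 8,
                       n_days = 14,
                       ema_days = NULL,
                       prompt_times = c("09:00", "12:00", "15:00", "18:00"),
                       gamma_within_hr = -0.12,
                       gamma_between_midpoint = -0.26,
                       gamma_within_tib = -0.10,
                       var_intercept = 0.69,
                       var_residual = 1,
                       chronotype_mean = 690,
                       chronotype_sd = 45,
                       regularity_sd_range = c(20, 80),
                       tib_mean = 480,
                       tib_sd = 45,
                       sleep_eff_mean = 0.92,
                       sleep_eff_sd = 0.03,
                       base_hr_mean = 62,
                       base_hr_sd = 6,
                       hr_night_sd = 3,
                       hr_sample_sd = 2,
                       wake_hr_offset = 15,
                       split_prob = 0.1,
                       missing_wear_rate = 0.12,
                       nonresponse_rate = 0.1266,
                       latency_meanlog = log(11.8),
                       latency_sdlog = 1.9,
                       questionnaire_noise_sd = 2,
                       questionnaire_effect_scale = 1,
                       start_date = "2022-02-01",
                       paper_scale = FALSE,
                       seed = 1L) {
  if (isTRUE(paper_scale)) {
    n_participants <- 40L
    n_days <- 56L
  }
  if (length(seed) != 1 || !is.finite(suppressWarnings(as.numeric(seed))) ||
      as.numeric(seed) < 0 || as.numeric(seed) > 2^31 - 32)
    cfg_err("seed", "must be a non-negative integer below 2^31 - 32")
  cfg <- list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    ema_days = ema_days, prompt_times = prompt_times,
    gamma_within_hr = gamma_within_hr,
    gamma_between_midpoint = gamma_between_midpoint,
    gamma_within_tib = gamma_within_tib,
    var_intercept = var_intercept, var_residual = var_residual,
    chronotype_mean = chronotype_mean, chronotype_sd = chronotype_sd,
    regularity_sd_range = regularity_sd_range,
    tib_mean = tib_mean, tib_sd = tib_sd,
    sleep_eff_mean = sleep_eff_mean, sleep_eff_sd = sleep_eff_sd,
    base_hr_mean = base_hr_mean, base_hr_sd = base_hr_sd,
    hr_night_sd = hr_night_sd, hr_sample_sd = hr_sample_sd,
    wake_hr_offset = wake_hr_offset,
    split_prob = split_prob,
    missing_wear_rate = missing_wear_rate,
    nonresponse_rate = nonresponse_rate,
    latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
    questionnaire_noise_sd = questionnaire_noise_sd,
    questionnaire_effect_scale = questionnaire_effect_scale,
    start_date = as_ema_date(start_date),
    seed = as.integer(seed)
  )
  if (is.null(cfg$ema_days)) cfg$ema_days <- default_ema_days(cfg$n_days)
  cfg$ema_days <- as.integer(sort(unique(cfg$ema_days)))
  validate_gen_config(cfg)
  structure(cfg, class = "ema_gen_config")
}

# Default EMA schedule: two non-consecutive weekdays per week in weeks 1-2
# and 7-8 when the study is long enough, otherwise 8 days spread over the
# span. Day indices are nights-available days, so day 1 is never prompted.
default_ema_days <- function(n_days) {
  if (n_days >= 56) return(c(2L, 4L, 9L, 11L, 44L, 46L, 51L, 53L))
  k <- min(8L, n_days - 1L)
  unique(as.integer(round(seq(2L, n_days, length.out = k))))
}

cfg_err <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

validate_gen_config <- function(cfg) {
  if (cfg$n_participants < 2) cfg_err("n_participants", "must be >= 2")
  if (cfg$n_days < 2) cfg_err("n_days", "must be >= 2")
  if (any(cfg$ema_days < 2) || any(cfg$ema_days > cfg$n_days))
    cfg_err("ema_days", "must lie in [2, n_days] (day 1 has no previous night)")
  pt <- prompt_minutes(cfg$prompt_times)
  if (any(diff(pt) <= 0))
    cfg_err("prompt_times", "must be strictly increasing within the day")
  for (f in c("var_intercept", "var_residual", "chronotype_sd", "tib_sd",
              "sleep_eff_sd", "base_hr_sd", "hr_night_sd", "hr_sample_sd",
              "questionnaire_noise_sd")) {
    if (cfg[[f]] < 0) cfg_err(f, "must be >= 0")
  }
  if (cfg$var_intercept + cfg$var_residual <= 0)
    cfg_err("var_residual", "variance weights must not both be 0")
  for (f in c("split_prob", "missing_wear_rate", "nonresponse_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) cfg_err(f, "must be a probability in [0, 1]")
  }
  rng <- cfg$regularity_sd_range
  if (length(rng) != 2 || any(rng <= 0) || rng[2] < rng[1])
    cfg_err("regularity_sd_range", "must be (min, max) with 0 < min <= max")
  g2 <- cfg$gamma_within_hr^2 + cfg$gamma_between_midpoint^2 + cfg$gamma_within_tib^2
  if (g2 >= 1)
    cfg_err("gamma_within_hr", "squared slopes must sum to < 1 (unit latent variance)")
  if (is.na(cfg$seed) || cfg$seed < 0 || cfg$seed > 2^31 - 32)
    cfg_err("seed", "must be a non-negative integer below 2^31 - 32")
  invisible(cfg)
}

prompt_minutes <- function(prompt_times) {
  parts <- strsplit(prompt_times, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

#' Load a run configuration from JSON or YAML
#'
#' Reads a (possibly empty) JSON or YAML document, rejects unknown keys, and
#' fills every other field from the [gen_config()] defaults. The effective
#' configuration is echoed to the console via `message()`.
#'
#' @param path path to a `.json`, `.yaml`/`.yml` file.
#' @param quiet suppress the echo of the effective configuration.
#' @return a validated `"ema_gen_config"`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of keys to values", call. = FALSE)
  known <- names(formals(gen_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(sprintf("\"%s\"", unknown), collapse = ", ")), call. = FALSE)
  cfg <- do.call(gen_config, raw)
  if (!quiet) {
    scalars <- vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                      character(1))
    message("effective config: ",
            paste(sprintf("%s=%s", names(scalars), scalars), collapse = "; "))
  }
  cfg
}
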