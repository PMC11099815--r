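# Pipeline orchestration: simulate -> features -> analyze -> report.
#
# Each stage reads and writes plain CSV/JSON in a run directory and records
# a manifest (config hash, seed, row counts, file digests) so identical
# configs produce identical runs.

manifest_write <- function(dir, stage, config = NULL, counts = list(),
                           files = character()) {
  digests <- vapply(files, function(f)
    unname(tools::md5sum(f)), character(1))
  config_hash <- NULL
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".txt")
    writeLines(deparse(unclass(config)), tf)
    config_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  m <- list(stage = stage,
            config_hash = config_hash,
            seed = if (!is.null(config)) config$seed else NULL,
            row_counts = counts,
            files = as.list(digests))
  jsonlite::write_json(m, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(m)
}

#' Simulate a study and write its data directory
#'
#' Writes the five standard tables plus `participants.csv` (demographics)
#' and `ground_truth.json` (generating parameters and per-participant
#' traits) to `out_dir`.
#'
#' @param config a [gen_config()].
#' @param out_dir output directory (created).
#' @param streams write the large 5-second pulse and minute-activity streams.
#' @return invisibly, the simulated study list.
#' @export
cmd_simulate <- function(config = gen_config(), out_dir, streams = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config, streams = streams)
  write_sleep(study$sleep_records, file.path(out_dir, "sleep.csv"))
  write_ema(study$ema, file.path(out_dir, "ema.csv"))
  write_questionnaires(study$questionnaires, file.path(out_dir, "questionnaires.csv"))
  data.table::fwrite(study$traits[, c("participant_id", "age", "gender")],
                     file.path(out_dir, "participants.csv"))
  if (streams) {
    write_heart_rate(study$heart_rate, file.path(out_dir, "heart_rate.csv"))
    write_activity(study$activity, file.path(out_dir, "activity.csv"))
  }
  jsonlite::write_json(c(study$ground_truth, list(traits = study$traits)),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts <- list(sleep = nrow(study$sleep_records), ema = nrow(study$ema),
                 questionnaires = nrow(study$questionnaires))
  if (streams) counts$heart_rate <- nrow(study$heart_rate)
  manifest_write(out_dir, "simulate", config, counts,
                 file.path(out_dir, c("sleep.csv", "ema.csv", "questionnaires.csv")))
  invisible(study)
}

#' Derive features from a data directory
#'
#' Chains wear-validity coverage, night consolidation, weekly regularity,
#' windowed SDNN and nightly cardiac summaries, and the EMA observation
#' table; writes `coverage.csv`, `nights.csv`, `weekly_regularity.csv`,
#' `hrv_windows.csv`, `night_cardiac.csv`, `observations.csv` and
#' `adherence.json` to `out_dir`.
#'
#' @param data_dir directory written by [cmd_simulate()] (or real exports in
#'   the same dialect).
#' @param out_dir output directory (default `data_dir`).
#' @param strict abort on invalid rows instead of rejecting them.
#' @return invisibly, a list of the feature tables.
#' @export
cmd_features <- function(data_dir, out_dir = data_dir, strict = FALSE) {
  need <- c("sleep.csv", "ema.csv")
  for (f in need) if (!file.exists(file.path(data_dir, f)))
    stop("missing input file: ", file.path(data_dir, f), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sleep <- read_sleep(file.path(data_dir, "sleep.csv"), strict)
  ema <- read_ema(file.path(data_dir, "ema.csv"), strict)
  hr_path <- file.path(data_dir, "heart_rate.csv")
  act_path <- file.path(data_dir, "activity.csv")
  hr <- if (file.exists(hr_path)) read_heart_rate(hr_path, strict)
  act <- if (file.exists(act_path)) read_activity(act_path, strict)
  demo_path <- file.path(data_dir, "participants.csv")
  demo <- if (file.exists(demo_path)) as.data.frame(data.table::fread(demo_path))

  nights <- consolidate_nights(sleep)
  weekly <- weekly_regularity(nights)
  hrv <- if (!is.null(hr)) segment_and_summarize(hr, nights)
  cov <- if (!is.null(hr)) {
    span <- range(c(as.Date(ema$study_day), nights$night_date))
    daily_coverage(hr, dates = seq(span[1] - 1, span[2], by = 1))
  }
  obs <- build_observation_table(ema, act, hr, nights,
                                 if (!is.null(hrv)) hrv$night_cardiac, demo)
  utils::write.csv(nights[, setdiff(names(nights), "wake_time")],
                   file.path(out_dir, "nights.csv"), row.names = FALSE)
  utils::write.csv(weekly, file.path(out_dir, "weekly_regularity.csv"),
                   row.names = FALSE)
  if (!is.null(hrv)) {
    utils::write.csv(hrv$windows, file.path(out_dir, "hrv_windows.csv"),
                     row.names = FALSE)
    utils::write.csv(hrv$night_cardiac, file.path(out_dir, "night_cardiac.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cov))
    utils::write.csv(cov, file.path(out_dir, "coverage.csv"), row.names = FALSE)
  obs_out <- obs
  obs_out$response_time <- format_ema_time(obs_out$response_time)
  utils::write.csv(obs_out, file.path(out_dir, "observations.csv"),
                   row.names = FALSE)
  adherence <- if (!is.null(cov)) {
    ad <- adherence_summary(ema, cov, length(unique(ema$participant_id)),
                            length(unique(cov$date)))
    jsonlite::write_json(unclass(ad), file.path(out_dir, "adherence.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ad
  }
  manifest_write(out_dir, "features",
                 counts = list(nights = nrow(nights), weekly = nrow(weekly),
                               observations = nrow(obs)),
                 files = file.path(out_dir, c("nights.csv", "observations.csv")))
  invisible(list(nights = nights, weekly = weekly, hrv = hrv, coverage = cov,
                 observations = obs, adherence = adherence, ema = ema,
                 questionnaires = NULL))
}

#' Analyze a features directory
#'
#' Runs the quartile nonparametrics, the unconditional ICCs and the three
#' stepwise mixed models; writes `comparisons.csv`, `model_<outcome>.csv`,
#' `icc.json` and the run report.
#'
#' @param features a list returned by [cmd_features()], or a directory
#'   containing its CSV outputs plus `questionnaires.csv`.
#' @param questionnaires questionnaire table (needed when `features` is a
#'   list; read from the directory otherwise).
#' @param out_dir output directory.
#' @return invisibly, list with `comparisons`, `iccs`, `models`.
#' @export
cmd_analyze <- function(features, questionnaires = NULL, out_dir) {
  if (is.character(features)) {
    dirp <- features
    nights <- utils::read.csv(file.path(dirp, "nights.csv"))
    nights$night_date <- as.Date(nights$night_date)
    weekly <- utils::read.csv(file.path(dirp, "weekly_regularity.csv"))
    nc_p <- file.path(dirp, "night_cardiac.csv")
    night_cardiac <- if (file.exists(nc_p)) {
      x <- utils::read.csv(nc_p); x$night_date <- as.Date(x$night_date); x
    }
    hw_p <- file.path(dirp, "hrv_windows.csv")
    hrv_windows <- if (file.exists(hw_p)) {
      x <- utils::read.csv(hw_p); x$window_start <- as_ema_time(x$window_start); x
    }
    obs <- utils::read.csv(file.path(dirp, "observations.csv"))
    obs$response_time <- as_ema_time(obs$response_time)
    if (is.null(questionnaires))
      questionnaires <- read_questionnaires(file.path(dirp, "questionnaires.csv"))
    ema <- NULL; cov <- NULL
    adherence <- NULL
  } else {
    nights <- features$nights; weekly <- features$weekly
    night_cardiac <- features$hrv$night_cardiac
    hrv_windows <- features$hrv$windows
    obs <- features$observations
    adherence <- features$adherence
  }
  if (is.null(questionnaires)) stop("questionnaire table required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comparisons <- run_quartile_analysis(nights, weekly, night_cardiac,
                                       hrv_windows, questionnaires)
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  iccs <- lapply(c("energy", "mood", "sleepiness"), function(oc)
    icc_unconditional(obs, oc))
  jsonlite::write_json(lapply(iccs, function(ic) ic[c("outcome", "icc")]),
                       file.path(out_dir, "icc.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  models <- build_table_models(obs)
  for (oc in names(models)) {
    utils::write.csv(models[[oc]]$fit$fixed_effects,
                     file.path(out_dir, paste0("model_", oc, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(models[[oc]]$trace,
                         file.path(out_dir, paste0("aic_trace_", oc, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(adherence))
    write_report(adherence, comparisons, iccs, models, out_dir)
  invisible(list(comparisons = comparisons, iccs = iccs, models = models))
}

#' Run the full pipeline
#'
#' simulate -> features -> analyze -> report, all under one run directory.
#'
#' @param config a [gen_config()].
#' @param out_dir run directory.
#' @param streams simulate the large device streams (required for HRV and
#'   wear filtering; `FALSE` restricts the run to sleep-based analyses).
#' @return invisibly, the [cmd_analyze()] result.
#' @export
cmd_all <- function(config = gen_config(), out_dir, streams = TRUE) {
  study <- cmd_simulate(config, file.path(out_dir, "data"), streams = streams)
  feats <- cmd_features(file.path(out_dir, "data"), file.path(out_dir, "features"))
  res <- cmd_analyze(feats, study$questionnaires, file.path(out_dir, "analysis"))
  if (!is.null(feats$adherence))
    write_report(feats$adherence, res$comparisons, res$iccs, res$models,
                 file.path(out_dir, "analysis"))
  invisible(res)
}
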