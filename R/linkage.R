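# Linking EMA responses to prior-hour activity and previous-night sleep.

#' Prior-hour activity aggregates for one response
#'
#' Aggregates device activity over the half-open hour `[t - 60 min, t)`
#' ending at the response time: summed MET-minutes, summed steps, and mean
#' pulse rate. Missing when no data fall in the window.
#'
#' @param response_time the EMA response timestamp.
#' @param activity minute-activity table for the participant.
#' @param samples heart-rate sample table for the participant (optional).
#' @return list `met_sum_1h`, `steps_1h`, `mean_hr_1h`.
#' @export
match_prior_activity <- function(response_time, activity, samples = NULL) {
  rt <- as_ema_time(response_time)
  w0 <- rt - 3600
  out <- list(met_sum_1h = NA_real_, steps_1h = NA_real_, mean_hr_1h = NA_real_)
  if (!is.null(activity) && nrow(activity)) {
    in_w <- activity$minute_start >= w0 & activity$minute_start < rt
    if (any(in_w)) {
      out$met_sum_1h <- sum(activity$mets[in_w])
      out$steps_1h <- sum(activity$steps[in_w])
    }
  }
  if (!is.null(samples) && nrow(samples)) {
    in_s <- samples$timestamp >= w0 & samples$timestamp < rt
    if (any(in_s)) out$mean_hr_1h <- mean(samples$bpm[in_s])
  }
  out
}

#' Previous-night sleep for a response date
#'
#' Returns the consolidated night whose wake time falls in the matching
#' window from 18:00 on the day before the response date to 09:00 on the
#' response date (both endpoints closed); missing when no night qualifies.
#' Consolidation guarantees at most one night per window.
#'
#' @param response_date the EMA response date.
#' @param nights consolidated nights for the participant.
#' @return one-row data.frame or `NULL`.
#' @export
match_previous_sleep <- function(response_date, nights) {
  d <- as_ema_date(response_date)
  w0 <- clock_time_of(d - 1L, "18:00")
  w1 <- clock_time_of(d, "09:00")
  hit <- nights$wake_time >= w0 & nights$wake_time <= w1
  if (!any(hit)) return(NULL)
  if (sum(hit) > 1)
    stop("multiple consolidated nights match one window; consolidation bug",
         call. = FALSE)
  nights[hit, , drop = FALSE]
}

#' Build the EMA observation (modeling) table
#'
#' One row per answered prompt whose response arrived on the scheduled study
#' day (late responses past midnight are dropped), carrying the three VAS
#' outcomes, prior-hour activity aggregates, the matched previous night's
#' sleep indices and nightly cardiac summary, demographics when supplied,
#' and the two wear-filter flags (`pre_ema_ok`: strict >80% in the prior
#' hour; `overnight_ok`: >=80% from 18:00 the day before to 09:00). When no
#' pulse stream is supplied the filter flags are `NA` and no rows are
#' excluded on wear.
#'
#' @param ema EMA response table (see [read_ema()]).
#' @param activity minute-activity table or `NULL`.
#' @param samples heart-rate sample table or `NULL`.
#' @param nights consolidated nights ([consolidate_nights()]).
#' @param night_cardiac nightly cardiac table ([segment_and_summarize()])
#'   or `NULL`.
#' @param demographics optional data.frame `participant_id`, `age`, `gender`.
#' @param apply_filters drop rows failing the wear filter relevant to each
#'   feature set: rows failing the pre-EMA filter lose concurrent aggregates,
#'   rows failing the overnight filter lose sleep predictors (features are
#'   set missing rather than rows dropped; set to `"drop"` to remove rows
#'   failing either filter, or `FALSE` to keep everything flagged only).
#' @param threshold wear-filter threshold (default 0.80).
#' @return data.frame, one row per usable EMA observation.
#' @export
build_observation_table <- function(ema, activity = NULL, samples = NULL,
                                    nights, night_cardiac = NULL,
                                    demographics = NULL,
                                    apply_filters = TRUE, threshold = 0.80) {
  obs <- ema[!is.na(ema$response_time), , drop = FALSE]
  same_day <- as.Date(obs$response_time, tz = ema_tz) == as_ema_date(obs$study_day)
  obs <- obs[same_day, , drop = FALSE]
  if (nrow(obs) == 0) stop("no usable EMA observations", call. = FALSE)
  obs$slot <- match(obs$scheduled_time,
                    sort(unique(obs$scheduled_time)))

  act_split <- if (!is.null(activity)) split(activity, activity$participant_id)
  smp_split <- if (!is.null(samples)) split(samples, samples$participant_id)
  nights_split <- split(nights, nights$participant_id)

  n <- nrow(obs)
  met <- steps <- mhr <- rep(NA_real_, n)
  pre_ok <- on_ok <- rep(NA, n)
  night_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- obs$participant_id[i]
    agg <- match_prior_activity(obs$response_time[i],
                                if (!is.null(act_split)) act_split[[pid]],
                                if (!is.null(smp_split)) smp_split[[pid]])
    met[i] <- agg$met_sum_1h; steps[i] <- agg$steps_1h; mhr[i] <- agg$mean_hr_1h
    if (!is.null(smp_split)) {
      ps <- smp_split[[pid]]
      if (is.null(ps)) ps <- data.frame(timestamp = as.POSIXct(character(), tz = ema_tz))
      pre_ok[i] <- passes_pre_ema_filter(ps, obs$response_time[i], threshold)
      on_ok[i] <- passes_overnight_filter(ps, as.Date(obs$response_time[i], tz = ema_tz),
                                          threshold)
    }
    pn <- nights_split[[pid]]
    night_rows[i] <- list(if (!is.null(pn))
      match_previous_sleep(as.Date(obs$response_time[i], tz = ema_tz), pn))
  }
  empty_night <- data.frame(night_date = as.Date(NA), bedtime = NA_real_,
                            tib_min = NA_real_, sleep_min = NA_real_,
                            efficiency_pct = NA_real_, midpoint = NA_real_)
  night_df <- do.call(rbind, lapply(night_rows, function(r) {
    if (is.null(r)) empty_night
    else r[, c("night_date", "bedtime", "tib_min", "sleep_min",
               "efficiency_pct", "midpoint")]
  }))
  out <- cbind(obs[, c("participant_id", "study_day", "scheduled_time",
                       "response_time", "slot", "sleepiness", "mood", "energy")],
               data.frame(met_sum_1h = met, steps_1h = steps, mean_hr_1h = mhr,
                          pre_ema_ok = pre_ok, overnight_ok = on_ok),
               night_df)
  if (!is.null(night_cardiac)) {
    nc <- night_cardiac[, c("participant_id", "night_date", "mean_sleep_hr",
                            "sleep_sdnn_ms")]
    out <- merge(out, nc, by = c("participant_id", "night_date"),
                 all.x = TRUE, sort = FALSE)
  } else {
    out$mean_sleep_hr <- NA_real_
    out$sleep_sdnn_ms <- NA_real_
  }
  if (!is.null(demographics))
    out <- merge(out, demographics[, c("participant_id", "age", "gender")],
                 by = "participant_id", all.x = TRUE, sort = FALSE)
  if (identical(apply_filters, "drop")) {
    out <- out[(is.na(out$pre_ema_ok) | out$pre_ema_ok) &
                 (is.na(out$overnight_ok) | out$overnight_ok), , drop = FALSE]
  } else if (isTRUE(apply_filters)) {
    fail_pre <- !is.na(out$pre_ema_ok) & !out$pre_ema_ok
    out$met_sum_1h[fail_pre] <- NA_real_
    out$steps_1h[fail_pre] <- NA_real_
    out$mean_hr_1h[fail_pre] <- NA_real_
    fail_on <- !is.na(out$overnight_ok) & !out$overnight_ok
    for (v in c("bedtime", "tib_min", "sleep_min", "efficiency_pct", "midpoint",
                "mean_sleep_hr", "sleep_sdnn_ms"))
      out[[v]][fail_on] <- NA_real_
  }
  out <- out[order(out$participant_id, out$response_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
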