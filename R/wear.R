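# Wear-time coverage and the three 80% validity filters.
#
# "Worn" is defined at minute resolution: a minute counts as worn iff at
# least one heart-rate sample falls in it. The three filters keep the
# literal inclusivity of their definitions: a valid record day needs
# coverage of *at least* 80% (inclusive); the pre-EMA hour needs coverage
# *exceeding* 80% (strict); the overnight window needs *80% or greater*
# (inclusive).

worn_minutes_in <- function(timestamps, start, end) {
  t <- as.numeric(timestamps)
  s <- as.numeric(start); e <- as.numeric(end)
  t <- t[t >= s & t < e]
  length(unique(floor(t / 60)))
}

#' Minute-resolution wear coverage over an interval
#'
#' @param samples heart-rate sample table (one participant) with a
#'   `timestamp` column.
#' @param interval_start,interval_end the half-open interval
#'   `[start, end)` over which coverage is computed.
#' @return list with `minutes_total`, `minutes_worn` and `coverage`
#'   (exact fraction `minutes_worn / minutes_total`).
#' @export
minute_coverage <- function(samples, interval_start, interval_end) {
  interval_start <- as_ema_time(interval_start)
  interval_end <- as_ema_time(interval_end)
  total <- diff_minutes(interval_end, interval_start)
  if (is.na(total) || total <= 0)
    stop("empty or ill-formed coverage interval", call. = FALSE)
  worn <- worn_minutes_in(samples$timestamp, interval_start, interval_end)
  list(minutes_total = as.integer(round(total)), minutes_worn = worn,
       coverage = worn / round(total))
}

#' Valid record day: coverage of at least 80%
#'
#' @param coverage a [minute_coverage()] result or a bare fraction.
#' @param threshold inclusive validity threshold (default 0.80).
#' @return logical.
#' @export
is_valid_record_day <- function(coverage, threshold = 0.80) {
  cov <- if (is.list(coverage)) coverage$coverage else coverage
  cov >= threshold
}

#' Pre-EMA wear filter: coverage exceeding 80% in the prior hour
#'
#' Coverage over the 60 minutes ending at the response time
#' (`[t - 60 min, t)`); passes only when coverage is *strictly* above the
#' threshold, so 48/60 worn minutes (exactly 0.80) fails.
#'
#' @param samples heart-rate samples for the participant.
#' @param response_time EMA response timestamp.
#' @param threshold strict threshold (default 0.80).
#' @return logical.
#' @export
passes_pre_ema_filter <- function(samples, response_time, threshold = 0.80) {
  rt <- as_ema_time(response_time)
  cov <- minute_coverage(samples, rt - 3600, rt)
  cov$coverage > threshold
}

#' Overnight wear filter: coverage of 80% or greater, 18:00 to 09:00
#'
#' Coverage over the 15-hour window from 18:00 on the day before the
#' response date to 09:00 on the response date; passes when coverage is at
#' least the threshold (inclusive), so 720/900 worn minutes passes.
#'
#' @param samples heart-rate samples for the participant.
#' @param response_date the EMA response date.
#' @param threshold inclusive threshold (default 0.80).
#' @return logical.
#' @export
passes_overnight_filter <- function(samples, response_date, threshold = 0.80) {
  d <- as_ema_date(response_date)
  cov <- minute_coverage(samples, clock_time_of(d - 1L, "18:00"),
                         clock_time_of(d, "09:00"))
  cov$coverage >= threshold
}

#' Per-participant-day wear coverage table
#'
#' @param samples heart-rate sample table (any number of participants).
#' @param dates optional vector of dates; default spans each participant's
#'   observed range.
#' @param threshold inclusive valid-day threshold.
#' @return data.frame `participant_id`, `date`, `minutes_worn`,
#'   `minutes_total` (1440), `coverage`, `valid_day`.
#' @export
daily_coverage <- function(samples, dates = NULL, threshold = 0.80) {
  dt <- data.table::as.data.table(samples)
  dt[, minute := floor(as.numeric(timestamp) / 60)]
  dt <- unique(dt[, .(participant_id, minute)])
  dt[, date := as.Date(as.POSIXct(minute * 60, origin = "1970-01-01", tz = ema_tz))]
  cov <- dt[, .(minutes_worn = .N), by = .(participant_id, date)]
  if (!is.null(dates)) {
    grid <- data.table::CJ(participant_id = unique(samples$participant_id),
                           date = as_ema_date(dates))
    cov <- cov[grid, on = c("participant_id", "date")]
    cov[is.na(minutes_worn), minutes_worn := 0L]
  }
  cov[, minutes_total := 1440L]
  cov[, coverage := minutes_worn / 1440]
  cov[, valid_day := coverage >= threshold]
  data.table::setorder(cov, participant_id, date)
  as.data.frame(cov)
}
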