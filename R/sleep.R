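# Per-night sleep consolidation and regularity statistics.
#
# A "night" is anchored to the date of its wake time: records waking before
# noon belong to that morning's date, records waking in the evening (after a
# nap or an early split segment) to the following date — i.e. every record
# belongs to the [18:00 previous day, 09:00 day] matching window of exactly
# one anchor date when it falls inside one.

# Anchor date for a wake time.
night_anchor <- function(wake_time) {
  d <- as.Date(wake_time, tz = ema_tz)
  hour <- as.numeric(format(wake_time, "%H", tz = ema_tz))
  d + (hour >= 12)
}

# Union length (minutes) of a set of [start, end] intervals.
interval_union_minutes <- function(start, end) {
  o <- order(start)
  s <- as.numeric(start)[o]; e <- as.numeric(end)[o]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { total <- total + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  (total + (cur_e - cur_s)) / 60
}

#' Consolidate the sleep records of one night
#'
#' Merges all in-bed records whose wake times fall in one participant-night
#' matching window into a single night: bedtime is the earliest in-bed
#' start, wake the latest in-bed end, time in bed (TIB) the total length of
#' the *union* of the in-bed intervals (overlaps are not double counted),
#' sleep duration the sum of asleep minutes capped at TIB, sleep efficiency
#' `100 * sleep / TIB`, and the midpoint of sleep the temporal midpoint of
#' the full consolidated span. Bedtime and midpoint are encoded as minutes
#' after noon of the sleep-onset day ([clock_encode()]).
#'
#' @param records data.frame of raw sleep records (see [read_sleep()]) for
#'   one participant-night.
#' @return one-row data.frame: `participant_id`, `night_date`, `bedtime`,
#'   `wake_time`, `tib_min`, `sleep_min`, `efficiency_pct`, `midpoint`,
#'   `n_records`.
#' @examples
#' recs <- data.frame(participant_id = "P1",
#'   bed_start = as.POSIXct(c("2022-02-01 22:30:00", "2022-02-02 02:00:00"),
#'                          tz = "UTC"),
#'   bed_end = as.POSIXct(c("2022-02-02 01:00:00", "2022-02-02 06:30:00"),
#'                        tz = "UTC"),
#'   minutes_asleep = c(130, 250))
#' consolidate_night(recs)  # tib 420, sleep 380, efficiency 90.48, midpoint 02:30
#' @export
consolidate_night <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot consolidate an empty record list", call. = FALSE)
  bed_start <- min(records$bed_start)
  wake_time <- max(records$bed_end)
  onset_date <- as.Date(bed_start, tz = ema_tz) -
    (as.numeric(format(bed_start, "%H", tz = ema_tz)) < 12)
  tib <- interval_union_minutes(records$bed_start, records$bed_end)
  sleep <- min(sum(records$minutes_asleep), tib)
  span_mid <- bed_start + as.numeric(difftime(wake_time, bed_start, units = "secs")) / 2
  data.frame(
    participant_id = records$participant_id[1],
    night_date = night_anchor(wake_time),
    bedtime = clock_encode(bed_start, onset_date),
    wake_time = wake_time,
    tib_min = tib,
    sleep_min = sleep,
    efficiency_pct = 100 * sleep / tib,
    midpoint = clock_encode(span_mid, onset_date),
    n_records = nrow(records),
    stringsAsFactors = FALSE
  )
}

#' Consolidate all raw sleep records into per-night indices
#'
#' Groups records by participant and wake-anchor date and applies
#' [consolidate_night()] to each group.
#'
#' @param records raw sleep-record table (any number of participants).
#' @return data.frame of consolidated nights, sorted by participant and
#'   night date, with the in-bed intervals attached as attribute
#'   `"intervals"` (`participant_id`, `night_date`, `int_start`, `int_end`).
#' @export
consolidate_nights <- function(records) {
  if (nrow(records) == 0) stop("no sleep records", call. = FALSE)
  anchor <- night_anchor(records$bed_end)
  key <- split(seq_len(nrow(records)), list(records$participant_id,
                                            format(anchor)), drop = TRUE)
  nights <- do.call(rbind, lapply(key, function(ix)
    consolidate_night(records[ix, , drop = FALSE])))
  nights <- nights[order(nights$participant_id, nights$night_date), ]
  rownames(nights) <- NULL
  ints <- data.frame(participant_id = records$participant_id,
                     night_date = anchor,
                     int_start = records$bed_start, int_end = records$bed_end,
                     stringsAsFactors = FALSE)
  ints <- ints[order(ints$participant_id, ints$int_start), ]
  rownames(ints) <- NULL
  attr(nights, "intervals") <- ints
  nights
}

#' Weekly standard deviation of the sleep midpoint
#'
#' A sleep-regularity metric: the sample SD (n - 1 denominator) of the
#' nightly sleep midpoints within consecutive 7-day blocks counted from the
#' study start. Weeks with fewer than `min_nights` nights yield a missing
#' SD rather than an unstable one.
#'
#' @param nights consolidated nights (needs `participant_id`, `night_date`,
#'   `midpoint`).
#' @param start_date date of the first study morning; blocks are
#'   `[start, start + 7)`, etc. Defaults to each participant's first night.
#' @param min_nights minimum nights per week for a defined SD (default 3).
#' @return data.frame `participant_id`, `week_index`, `n_nights`,
#'   `midpoint_sd_min` (NA when under-observed).
#' @export
weekly_regularity <- function(nights, start_date = NULL, min_nights = 3) {
  stopifnot(all(c("participant_id", "night_date", "midpoint") %in% names(nights)))
  dt <- data.table::as.data.table(nights)
  if (is.null(start_date)) {
    dt[, week_index := as.integer(floor(as.numeric(night_date - min(night_date)) / 7)) + 1L,
       by = participant_id]
  } else {
    origin <- as_ema_date(start_date)
    dt[, week_index := as.integer(floor(as.numeric(night_date - origin) / 7)) + 1L]
  }
  out <- dt[, .(n_nights = .N,
                midpoint_sd_min = if (.N >= min_nights) stats::sd(midpoint) else NA_real_),
            by = .(participant_id, week_index)]
  data.table::setorder(out, participant_id, week_index)
  as.data.frame(out)
}

#' Per-participant sleep summary
#'
#' Person-level means of the nightly indices plus the mean weekly midpoint
#' SD; participants with zero valid nights are excluded with a warning.
#'
#' @param nights consolidated nights.
#' @param weekly optional output of [weekly_regularity()]; computed when
#'   omitted.
#' @return data.frame, one row per participant: means of `bedtime`,
#'   `midpoint`, `tib_min`, `sleep_min`, `efficiency_pct`,
#'   `mean_weekly_midpoint_sd`, and `n_nights`.
#' @export
person_sleep_summary <- function(nights, weekly = NULL) {
  ok <- !is.na(nights$midpoint)
  if (!all(ok)) warning(sum(!ok), " night(s) without a midpoint excluded")
  nights <- nights[ok, , drop = FALSE]
  if (nrow(nights) == 0) stop("no valid nights", call. = FALSE)
  if (is.null(weekly)) weekly <- weekly_regularity(nights)
  dt <- data.table::as.data.table(nights)
  out <- dt[, .(n_nights = .N, bedtime = mean(bedtime), midpoint = mean(midpoint),
                tib_min = mean(tib_min), sleep_min = mean(sleep_min),
                efficiency_pct = mean(efficiency_pct)),
            by = participant_id]
  wk <- data.table::as.data.table(weekly)[
    , .(mean_weekly_midpoint_sd = mean(midpoint_sd_min, na.rm = TRUE)),
    by = participant_id]
  out <- wk[out, on = "participant_id"]
  data.table::setcolorder(out, c("participant_id", "n_nights"))
  data.table::setorder(out, participant_id)
  as.data.frame(out)
}
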