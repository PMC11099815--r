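# SDNN heart-rate-variability features from 5-second pulse-rate samples.
#
# The device reports a rate (bpm) every 5 seconds rather than beat-to-beat
# intervals, so NN intervals are approximated as 60000/bpm milliseconds and
# SDNN as the sample SD of those values within 15-minute windows aligned to
# clock quarter-hours. This is an approximation to true beat-to-beat SDNN,
# not a replacement for ECG-derived values.

#' Convert a pulse rate to an approximate NN interval
#'
#' @param bpm pulse rate(s), beats per minute; must be positive.
#' @return NN interval(s) in milliseconds, `60000 / bpm`.
#' @examples
#' bpm_to_nn(60)  # 1000
#' bpm_to_nn(75)  # 800
#' @export
bpm_to_nn <- function(bpm) {
  if (any(is.na(bpm)) || any(bpm <= 0))
    stop("bpm must be positive", call. = FALSE)
  60000 / bpm
}

#' SDNN of one 15-minute window
#'
#' Sample SD (n - 1 denominator) of the derived NN intervals over the
#' samples of a single window. Windows with fewer than `min_samples`
#' samples (default 144 = 80% of the nominal 180 at 5-second cadence) yield
#' a missing SDNN.
#'
#' @param bpm pulse-rate samples within one window.
#' @param min_samples minimum sample count for a defined value.
#' @return list `n_samples`, `mean_bpm`, `sdnn_ms` (NA when under-sampled).
#' @export
sdnn_window <- function(bpm, min_samples = 144) {
  n <- length(bpm)
  list(n_samples = n,
       mean_bpm = if (n > 0) mean(bpm) else NA_real_,
       sdnn_ms = if (n >= max(min_samples, 2)) stats::sd(bpm_to_nn(bpm)) else NA_real_)
}

#' Windowed SDNN and nightly cardiac summaries
#'
#' Partitions each participant's samples into 15-minute windows on the
#' quarter-hour clock grid, computes the SDNN and mean rate of each window,
#' labels a window `sleep` when its midpoint lies inside a consolidated
#' in-bed interval (`wake` otherwise), and summarises each night: the mean
#' rate over all samples inside the night's in-bed intervals and the
#' unweighted mean of the night's valid sleep-window SDNNs.
#'
#' @param samples heart-rate sample table.
#' @param nights consolidated nights from [consolidate_nights()] (its
#'   `"intervals"` attribute supplies the in-bed intervals; a raw
#'   sleep-record table is also accepted and consolidated on the fly).
#' @param min_samples minimum samples per window (default 144).
#' @return list with `windows` (participant_id, window_start, n_samples,
#'   mean_bpm, sdnn_ms, context) and `night_cardiac` (participant_id,
#'   night_date, mean_sleep_hr, sleep_sdnn_ms, n_windows).
#' @export
segment_and_summarize <- function(samples, nights, min_samples = 144) {
  ints <- attr(nights, "intervals")
  if (is.null(ints)) {
    if (all(c("bed_start", "bed_end") %in% names(nights)))
      ints <- attr(consolidate_nights(nights), "intervals")
    else stop("`nights` must come from consolidate_nights() or be raw sleep records",
              call. = FALSE)
  }
  dt <- data.table::as.data.table(samples)
  dt[, window_start := floor(as.numeric(timestamp) / 900) * 900]
  win <- dt[, .(n_samples = .N, mean_bpm = mean(bpm),
                sdnn_ms = if (.N >= max(min_samples, 2)) stats::sd(60000 / bpm)
                          else NA_real_),
            by = .(participant_id, window_start)]
  win[, mid := window_start + 450]

  idt <- data.table::as.data.table(ints)
  idt[, `:=`(s = as.numeric(int_start), e = as.numeric(int_end))]
  data.table::setkey(idt, participant_id, s, e)
  win[, mid2 := mid]
  ov <- data.table::foverlaps(
    win[, .(participant_id, window_start, mid, mid2)],
    idt[, .(participant_id, s, e, night_date)],
    by.x = c("participant_id", "mid", "mid2"),
    by.y = c("participant_id", "s", "e"), type = "within", nomatch = NA)
  lab <- ov[, .(night_date = night_date[1]), by = .(participant_id, window_start)]
  win <- lab[win, on = c("participant_id", "window_start")]
  win[, context := ifelse(is.na(night_date), "wake", "sleep")]
  win[, `:=`(mid = NULL, mid2 = NULL)]
  win[, window_start := as.POSIXct(window_start, origin = "1970-01-01", tz = ema_tz)]
  data.table::setorder(win, participant_id, window_start)

  # nightly mean heart rate over all in-bed samples
  dt[, `:=`(ts = as.numeric(timestamp), ts2 = as.numeric(timestamp))]
  ovs <- data.table::foverlaps(
    dt[, .(participant_id, ts, ts2, bpm)],
    idt[, .(participant_id, s, e, night_date)],
    by.x = c("participant_id", "ts", "ts2"),
    by.y = c("participant_id", "s", "e"), type = "within", nomatch = NULL)
  hr_night <- ovs[, .(mean_sleep_hr = mean(bpm), n_bed_samples = .N),
                  by = .(participant_id, night_date)]
  sd_night <- win[context == "sleep" & !is.na(sdnn_ms),
                  .(sleep_sdnn_ms = mean(sdnn_ms), n_windows = .N),
                  by = .(participant_id, night_date)]
  nc <- sd_night[hr_night, on = c("participant_id", "night_date")]
  nc <- nc[!is.na(n_windows)]  # nights with zero valid windows are dropped
  data.table::setorder(nc, participant_id, night_date)
  list(windows = as.data.frame(win[, .(participant_id, window_start, n_samples,
                                       mean_bpm, sdnn_ms, context, night_date)]),
       night_cardiac = as.data.frame(nc[, .(participant_id, night_date,
                                            mean_sleep_hr, sleep_sdnn_ms,
                                            n_windows)]))
}
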