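# Time conventions used throughout the package.
#
# All timestamps are timezone-naive local time, represented as POSIXct in
# "UTC" (the study site has no daylight-saving shifts, so the offset never
# matters) and serialized as ISO 8601 "YYYY-MM-DDTHH:MM:SS".

#' @keywords internal
ema_tz <- "UTC"

as_ema_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- ema_tz
    return(x)
  }
  out <- as.POSIXct(x, tz = ema_tz,
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

as_ema_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

format_ema_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = ema_tz)

#' Minutes between two time points
#' @keywords internal
diff_minutes <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

# Floor a POSIXct to the start of its minute / its 15-minute grid window.
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = ema_tz)
}

floor_quarter_hour <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 900) * 900, origin = "1970-01-01", tz = ema_tz)
}

# Noon of a calendar date, as POSIXct.
noon_of <- function(date) {
  as.POSIXct(paste0(format(as_ema_date(date)), " 12:00:00"), tz = ema_tz)
}

clock_time_of <- function(date, hhmm) {
  as.POSIXct(paste0(format(as_ema_date(date)), " ", hhmm, ":00"), tz = ema_tz)
}

#' Encode a time point as minutes after noon of a reference day
#'
#' Sleep timing variables (bedtime, midpoint of sleep) wrap around midnight,
#' so they are encoded continuously as minutes elapsed since 12:00 noon of
#' the reference day on which the sleep episode starts: 23:00 maps to 660,
#' 02:36 on the following morning maps to 876.
#'
#' @param t a POSIXct time point (or string coercible to one).
#' @param reference_date the calendar date whose noon is the origin
#'   (typically the evening date of sleep onset).
#' @return numeric minutes after the reference noon.
#' @examples
#' clock_encode("2022-02-01 23:21:00", "2022-02-01")  # 681
#' clock_encode("2022-02-02 02:36:00", "2022-02-01")  # 876
#' @export
clock_encode <- function(t, reference_date) {
  diff_minutes(as_ema_time(t), noon_of(reference_date))
}

#' Decode minutes-after-noon back to a clock string
#'
#' Inverse of [clock_encode()] up to the calendar date: 681 becomes "23:21",
#' 876 becomes "02:36".
#'
#' @param minutes numeric minutes after noon.
#' @return "HH:MM" strings (on the 24-hour clock of whichever day the
#'   minutes land in).
#' @export
clock_decode <- function(minutes) {
  m <- (round(minutes) + 720) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
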