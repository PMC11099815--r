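# Tabular I/O for the five study tables.
#
# Dialect: UTF-8 CSV with header, ISO 8601 timestamps, one table per file.
# Loaders validate every row; offending rows are dropped and recorded in a
# parse report (attribute "parse_report"), or abort in strict mode.

table_schemas <- list(
  heart_rate = c("participant_id", "timestamp", "bpm"),
  activity = c("participant_id", "minute_start", "steps", "mets"),
  sleep = c("participant_id", "bed_start", "bed_end", "minutes_asleep"),
  ema = c("participant_id", "study_day", "scheduled_time", "response_time",
          "sleepiness", "mood", "energy"),
  questionnaires = c("participant_id", "instrument", "timepoint", "score")
)

check_schema <- function(df, kind) {
  want <- table_schemas[[kind]]
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("%s table: missing column(s) %s", kind,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[want]
}

finish_load <- function(df, bad, reasons, kind, strict, order_cols) {
  keep <- !bad
  if (any(bad) && strict) {
    stop(sprintf("%s table: %d invalid row(s), first: %s", kind, sum(bad),
                 reasons[which(bad)[1]]), call. = FALSE)
  }
  rejected <- data.frame(row = which(bad), reason = reasons[bad],
                         stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  out <- out[do.call(order, out[order_cols]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parse_report") <- list(rows_read = nrow(df), rows_kept = nrow(out),
                                    rows_rejected = sum(bad), rejected = rejected)
  out
}

#' Parse report of a loaded table
#' @param x a table returned by one of the `read_*` loaders.
#' @return list with `rows_read`, `rows_kept`, `rows_rejected` and a
#'   `rejected` data.frame of row indices and reasons.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Read / write the 5-second heart-rate sample table
#'
#' `heart_rate.csv` columns: `participant_id,timestamp,bpm`. Rows with `bpm`
#' outside (20, 250), unparseable timestamps, or duplicated
#' participant-timestamps are rejected (recorded in the parse report;
#' aborted in strict mode). Output is sorted by participant and time.
#'
#' @param path CSV file path.
#' @param strict abort on the first invalid row instead of rejecting it.
#' @return validated data.frame with a `"parse_report"` attribute.
#' @export
read_heart_rate <- function(path, strict = FALSE) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  df <- check_schema(df, "heart_rate")
  df$timestamp <- as_ema_time(df$timestamp)
  df$bpm <- as.numeric(df$bpm)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$timestamp)] <- "unparseable timestamp"
  reasons[is.na(df$bpm) | df$bpm <= 20 | df$bpm >= 250] <- "bpm out of range"
  dup <- duplicated(df[c("participant_id", "timestamp")]) & !is.na(df$timestamp)
  reasons[dup] <- "duplicate participant-timestamp"
  finish_load(df, !is.na(reasons), reasons, "heart_rate", strict,
              c("participant_id", "timestamp"))
}

#' @rdname read_heart_rate
#' @param x table to write.
#' @export
write_heart_rate <- function(x, path) {
  x <- check_schema(as.data.frame(x), "heart_rate")
  x$timestamp <- format_ema_time(x$timestamp)
  data.table::fwrite(x, path)
  invisible(path)
}

#' Read / write the minute-activity table
#'
#' `activity.csv` columns: `participant_id,minute_start,steps,mets`. Rows
#' with negative steps or METs, unparseable minutes, or duplicate
#' participant-minutes are rejected.
#'
#' @inheritParams read_heart_rate
#' @export
read_activity <- function(path, strict = FALSE) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  df <- check_schema(df, "activity")
  df$minute_start <- as_ema_time(df$minute_start)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$minute_start)] <- "unparseable minute_start"
  reasons[is.na(df$steps) | df$steps < 0] <- "steps negative or missing"
  reasons[is.na(df$mets) | df$mets < 0] <- "mets negative or missing"
  dup <- duplicated(df[c("participant_id", "minute_start")]) & !is.na(df$minute_start)
  reasons[dup] <- "duplicate participant-minute"
  finish_load(df, !is.na(reasons), reasons, "activity", strict,
              c("participant_id", "minute_start"))
}

#' @rdname read_activity
#' @param x table to write.
#' @export
write_activity <- function(x, path) {
  x <- check_schema(as.data.frame(x), "activity")
  x$minute_start <- format_ema_time(x$minute_start)
  data.table::fwrite(x, path)
  invisible(path)
}

#' Read / write the raw sleep-record table
#'
#' `sleep.csv` columns: `participant_id,bed_start,bed_end,minutes_asleep`.
#' Rows violating `bed_end > bed_start` or
#' `0 <= minutes_asleep <= in-bed minutes` are rejected.
#'
#' @inheritParams read_heart_rate
#' @export
read_sleep <- function(path, strict = FALSE) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  df <- check_schema(df, "sleep")
  df$bed_start <- as_ema_time(df$bed_start)
  df$bed_end <- as_ema_time(df$bed_end)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$bed_start) | is.na(df$bed_end)] <- "unparseable bed times"
  bad_order <- !is.na(df$bed_start) & !is.na(df$bed_end) & df$bed_end <= df$bed_start
  reasons[bad_order] <- "bed_end not after bed_start"
  tib <- diff_minutes(df$bed_end, df$bed_start)
  bad_asleep <- is.na(df$minutes_asleep) | df$minutes_asleep < 0 |
    (!is.na(tib) & df$minutes_asleep > tib)
  reasons[bad_asleep & is.na(reasons)] <- "minutes_asleep out of range"
  finish_load(df, !is.na(reasons), reasons, "sleep", strict,
              c("participant_id", "bed_start"))
}

#' @rdname read_sleep
#' @param x table to write.
#' @export
write_sleep <- function(x, path) {
  x <- check_schema(as.data.frame(x), "sleep")
  x$bed_start <- format_ema_time(x$bed_start)
  x$bed_end <- format_ema_time(x$bed_end)
  data.table::fwrite(x, path)
  invisible(path)
}

#' Read / write the EMA response table
#'
#' `ema.csv` columns:
#' `participant_id,study_day,scheduled_time,response_time,sleepiness,mood,energy`.
#' One row per scheduled prompt; unanswered prompts carry missing
#' `response_time` and VAS fields. Rows are rejected when the scheduled time
#' is not one of the known slots, when a present response time precedes the
#' scheduled time, when VAS values fall outside 0-100, or when response
#' presence and VAS presence disagree.
#'
#' @inheritParams read_heart_rate
#' @param prompt_times valid scheduled "HH:MM" slots.
#' @export
read_ema <- function(path, strict = FALSE,
                     prompt_times = c("09:00", "12:00", "15:00", "18:00")) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = 1),
                                        na.strings = c("", "NA")))
  df <- check_schema(df, "ema")
  df$study_day <- as_ema_date(df$study_day)
  df$response_time <- as_ema_time(as.character(df$response_time))
  for (v in c("sleepiness", "mood", "energy")) df[[v]] <- as.integer(df[[v]])
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$study_day)] <- "unparseable study_day"
  reasons[!(df$scheduled_time %in% prompt_times)] <- "unknown scheduled_time slot"
  sched <- clock_time_of(df$study_day, df$scheduled_time)
  answered <- !is.na(df$response_time)
  vas_present <- !is.na(df$sleepiness) & !is.na(df$mood) & !is.na(df$energy)
  vas_any <- !is.na(df$sleepiness) | !is.na(df$mood) | !is.na(df$energy)
  reasons[answered & !vas_present] <- "answered prompt with missing VAS"
  reasons[!answered & vas_any] <- "VAS present without response_time"
  early <- answered & !is.na(sched) & df$response_time < sched
  reasons[early & is.na(reasons)] <- "response_time before scheduled_time"
  for (v in c("sleepiness", "mood", "energy")) {
    bad <- !is.na(df[[v]]) & (df[[v]] < 0 | df[[v]] > 100)
    reasons[bad & is.na(reasons)] <- paste(v, "outside 0-100")
  }
  finish_load(df, !is.na(reasons), reasons, "ema", strict,
              c("participant_id", "study_day", "scheduled_time"))
}

#' @rdname read_ema
#' @param x table to write.
#' @export
write_ema <- function(x, path) {
  x <- check_schema(as.data.frame(x), "ema")
  x$study_day <- format(as_ema_date(x$study_day))
  x$response_time <- ifelse(is.na(x$response_time), NA_character_,
                            format_ema_time(x$response_time))
  data.table::fwrite(x, path)
  invisible(path)
}

#' Read / write the questionnaire score table
#'
#' `questionnaires.csv` columns:
#' `participant_id,instrument,timepoint,score`. Instruments must be one of
#' PSS, SWLS, SPANE-P, SPANE-N, FS-J, JESS and scores must fall in that
#' instrument's range (PSS 0-40, SWLS 5-35, SPANE 6-30, FS-J 8-56,
#' JESS 0-24); timepoint is `baseline` or `final`.
#'
#' @inheritParams read_heart_rate
#' @export
read_questionnaires <- function(path, strict = FALSE) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = 1)))
  df <- check_schema(df, "questionnaires")
  reasons <- rep(NA_character_, nrow(df))
  known <- df$instrument %in% names(instrument_ranges)
  reasons[!known] <- "unknown instrument"
  reasons[!(df$timepoint %in% c("baseline", "final"))] <- "unknown timepoint"
  rng <- do.call(rbind, instrument_ranges)[ifelse(known, df$instrument, "PSS"), ,
                                           drop = FALSE]
  bad_score <- is.na(df$score) | df$score < rng[, 1] | df$score > rng[, 2]
  reasons[known & bad_score & is.na(reasons)] <- "score outside instrument range"
  finish_load(df, !is.na(reasons), reasons, "questionnaires", strict,
              c("participant_id", "instrument", "timepoint"))
}

#' @rdname read_questionnaires
#' @param x table to write.
#' @export
write_questionnaires <- function(x, path) {
  x <- check_schema(as.data.frame(x), "questionnaires")
  data.table::fwrite(x, path)
  invisible(path)
}
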