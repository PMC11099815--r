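# Shared fixture builders (all data generated in code).

tz_ <- "UTC"

ts_ <- function(x) as.POSIXct(x, tz = tz_)

# Heart-rate samples covering the given minutes (one sample per minute by
# default, `per_min` for denser streams), for one participant.
hr_at_minutes <- function(minute_starts, bpm = 60, per_min = 1,
                          participant_id = "P1") {
  offs <- seq(0, 59, length.out = per_min)
  t <- as.vector(outer(offs, as.numeric(minute_starts), `+`))
  data.frame(participant_id = participant_id,
             timestamp = as.POSIXct(sort(t), origin = "1970-01-01", tz = tz_),
             bpm = bpm)
}

minutes_seq <- function(from, n) ts_(from) + 60 * (seq_len(n) - 1)

sleep_rec <- function(start, end, asleep, participant_id = "P1") {
  data.frame(participant_id = participant_id, bed_start = ts_(start),
             bed_end = ts_(end), minutes_asleep = asleep,
             stringsAsFactors = FALSE)
}

# A small all-answered EMA table with fixed latency, for counting tests.
ema_table <- function(ids, days, slots = c("09:00", "12:00", "15:00", "18:00"),
                      start_date = as.Date("2022-02-01"), latency_min = 10) {
  g <- expand.grid(slot = slots, day = days, participant_id = ids,
                   stringsAsFactors = FALSE)
  sched <- as.POSIXct(paste(start_date + g$day - 1, paste0(g$slot, ":00")), tz = tz_)
  data.frame(participant_id = g$participant_id,
             study_day = start_date + g$day - 1,
             scheduled_time = g$slot,
             response_time = sched + 60 * latency_min,
             sleepiness = 50L, mood = 50L, energy = 50L,
             stringsAsFactors = FALSE)
}

# Direct two-pass sample SD, the independent SDNN oracle.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
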