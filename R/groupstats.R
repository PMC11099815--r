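# Quartile stratification and nonparametric group comparison.
#
# Participants are split on questionnaire scores into a low group (minimum
# to first quartile) and a high group (third quartile to maximum), and
# night-level (or participant-week-level) sleep/HRV indices are compared
# between groups with the Mann-Whitney U test, Bonferroni adjustment over
# the metric family, and two effect sizes (Z-based r and Hedges g).

#' Quartile split of participants on a questionnaire score
#'
#' Quartiles use linear-interpolation quantiles (type 7); membership is
#' inclusive on both boundaries (`score <= Q1` low, `score >= Q3` high).
#'
#' @param scores questionnaire score table (see [read_questionnaires()]).
#' @param instrument instrument name, e.g. `"PSS"`.
#' @param timepoint `"baseline"` (default) or `"final"`.
#' @return list `instrument`, `q1`, `q3`, `low_ids`, `high_ids`.
#' @examples
#' qs <- data.frame(participant_id = sprintf("P%d", 1:8), instrument = "PSS",
#'                  timepoint = "baseline", score = 1:8)
#' quartile_split(qs, "PSS")  # Q1 2.75, Q3 6.25; low P1-P2, high P7-P8
#' @export
quartile_split <- function(scores, instrument, timepoint = "baseline") {
  s <- scores[scores$instrument == instrument & scores$timepoint == timepoint, ]
  if (nrow(s) < 4) stop("need at least 4 scored participants", call. = FALSE)
  q <- stats::quantile(s$score, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2])
    stop(sprintf("degenerate distribution for %s: Q1 == Q3", instrument),
         call. = FALSE)
  list(instrument = instrument, q1 = q[1], q3 = q[2],
       low_ids = s$participant_id[s$score <= q[1]],
       high_ids = s$participant_id[s$score >= q[2]])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (handles ties through the pooled ranks).
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

#' Mann-Whitney U test
#'
#' U from rank sums; Z via the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction. The two-sided p comes from full
#' enumeration of the permutation distribution when `n1 + n2 <= exact_max`
#' (default 12) and from the normal approximation otherwise.
#'
#' @param x,y numeric samples (the reported U counts pairs won by `x`).
#' @param exact_max largest combined sample size for the enumeration branch.
#' @return list `u`, `z`, `p`, `p_normal`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty", call. = FALSE)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) sign(u - mu) * max(0, abs(u - mu) - 0.5) / sqrt(sigma2) else 0
  p_normal <- min(1, 2 * stats::pnorm(-abs(z)))
  if (n <= exact_max) {
    list(u = u, z = z, p = mw_exact_p(x, y), p_normal = p_normal,
         method = "exact enumeration")
  } else {
    list(u = u, z = z, p = p_normal, p_normal = p_normal,
         method = "normal approximation")
  }
}

#' Z-based effect size r for a rank test
#'
#' @param z standardized test statistic.
#' @param n_total combined sample size.
#' @return `r = z / sqrt(n_total)` (sign follows the group order of the
#'   test).
#' @export
effect_size_r <- function(z, n_total) {
  if (is.na(n_total) || n_total <= 0) stop("n_total must be positive", call. = FALSE)
  z / sqrt(n_total)
}

#' Hedges g standardized mean difference
#'
#' Pooled-SD standardized difference of means with the small-sample
#' correction `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param x,y numeric samples (g is positive when `mean(x) > mean(y)`).
#' @return numeric g.
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 values per group", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled SD", call. = FALSE)
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean(x) - mean(y)) / sqrt(sp2)
}

#' Bonferroni adjustment
#'
#' @param p_raw raw p-value(s).
#' @param m family size (number of comparisons), >= 1.
#' @return `min(1, m * p_raw)`.
#' @export
bonferroni <- function(p_raw, m) {
  if (m < 1) stop("family size m must be >= 1", call. = FALSE)
  pmin(1, m * p_raw)
}

# Metric extractors: each returns data.frame(participant_id, value) at the
# pooling unit used for the group test (night level, participant-week level
# for the regularity metric, participant-day level for daytime SDNN).
metric_values <- function(metric, nights, weekly, night_cardiac, hrv_windows) {
  pick <- function(df, col) if (is.null(df)) NULL else
    stats::na.omit(data.frame(participant_id = df$participant_id, value = df[[col]]))
  switch(metric,
    bedtime = pick(nights, "bedtime"),
    midpoint = pick(nights, "midpoint"),
    tib_min = pick(nights, "tib_min"),
    sleep_min = pick(nights, "sleep_min"),
    efficiency_pct = pick(nights, "efficiency_pct"),
    midpoint_sd_min = pick(weekly, "midpoint_sd_min"),
    sleep_sdnn_ms = pick(night_cardiac, "sleep_sdnn_ms"),
    day_sdnn_ms = {
      if (is.null(hrv_windows)) NULL else {
        dt <- data.table::as.data.table(hrv_windows)
        dt <- dt[context == "wake" & !is.na(sdnn_ms)]
        if (nrow(dt) == 0) NULL else {
          dt[, date := as.Date(window_start, tz = ema_tz)]
          as.data.frame(dt[, .(value = mean(sdnn_ms)),
                           by = .(participant_id, date)][, .(participant_id, value)])
        }
      }
    },
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Quartile-group comparison of sleep and HRV indices
#'
#' For each instrument and metric, pools the metric's values over the
#' participants of the low- and high-score quartile groups and compares the
#' groups with [mann_whitney()]; attaches medians, the Bonferroni-adjusted p
#' (family = number of metrics actually compared per instrument), the
#' Z-based r (low - high direction) and Hedges g.
#'
#' @param nights consolidated nights.
#' @param weekly weekly regularity table ([weekly_regularity()]).
#' @param night_cardiac nightly cardiac table (optional).
#' @param hrv_windows HRV window table (optional; supplies daytime SDNN).
#' @param questionnaires questionnaire score table.
#' @param metrics metric names (default all eight indices).
#' @param instruments instruments to stratify on (default all six).
#' @param timepoint questionnaire timepoint for the split.
#' @param unit unit of analysis: `"pooled"` (default) pools the night-level
#'   (or participant-week-level) values of each group's participants;
#'   `"participant"` compares per-participant means. Pooling matches group
#'   medians of nightly values but treats clustered nights as independent,
#'   which inflates the type-I error when the index varies between persons
#'   (see the methods vignette).
#' @return data.frame, one row per instrument x metric, with `n_low`,
#'   `n_high`, `median_low`, `median_high`, `u_stat`, `z_stat`, `p_raw`,
#'   `m`, `p_adjusted`, `r_effect`, `hedges_g`, `method`.
#' @export
run_quartile_analysis <- function(nights, weekly = NULL, night_cardiac = NULL,
                                  hrv_windows = NULL, questionnaires,
                                  metrics = c("bedtime", "midpoint", "tib_min",
                                              "sleep_min", "efficiency_pct",
                                              "midpoint_sd_min", "sleep_sdnn_ms",
                                              "day_sdnn_ms"),
                                  instruments = names(instrument_ranges),
                                  timepoint = "baseline",
                                  unit = c("pooled", "participant")) {
  unit <- match.arg(unit)
  rows <- list()
  for (ins in instruments) {
    split <- tryCatch(quartile_split(questionnaires, ins, timepoint),
                      error = function(e) {
                        warning(ins, ": ", conditionMessage(e), "; skipped",
                                call. = FALSE)
                        NULL
                      })
    if (is.null(split)) next
    per_ins <- list()
    for (met in metrics) {
      vals <- metric_values(met, nights, weekly, night_cardiac, hrv_windows)
      if (is.null(vals) || nrow(vals) == 0) next
      if (unit == "participant") {
        agg <- tapply(vals$value, vals$participant_id, mean)
        vals <- data.frame(participant_id = names(agg), value = as.numeric(agg))
      }
      lo <- vals$value[vals$participant_id %in% split$low_ids]
      hi <- vals$value[vals$participant_id %in% split$high_ids]
      if (length(lo) < 2 || length(hi) < 2) {
        warning(sprintf("%s / %s: fewer than 2 observations in a group; skipped",
                        ins, met))
        next
      }
      mw <- mann_whitney(lo, hi)
      g <- tryCatch(hedges_g(lo, hi), error = function(e) NA_real_)
      per_ins[[met]] <- data.frame(
        instrument = ins, metric = met,
        n_low = length(lo), n_high = length(hi),
        median_low = stats::median(lo), median_high = stats::median(hi),
        u_stat = mw$u, z_stat = mw$z, p_raw = mw$p,
        r_effect = effect_size_r(mw$z, length(lo) + length(hi)),
        hedges_g = g, method = mw$method,
        stringsAsFactors = FALSE)
    }
    if (length(per_ins)) {
      tab <- do.call(rbind, per_ins)
      tab$m <- nrow(tab)
      tab$p_adjusted <- bonferroni(tab$p_raw, nrow(tab))
      rows[[ins]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
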