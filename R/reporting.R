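# Adherence summaries and the run report.

#' EMA and device adherence summary
#'
#' Response rate = 100 x answered / scheduled prompts; response latency
#' (response minus scheduled time) median and IQR in minutes; device
#' recovery rate = 100 x recorded worn minutes / expected minutes, where
#' expected = participants x days x 1440; and the mean (SD) daily wear time
#' in minutes. Percentages are rounded to 2 decimals.
#'
#' @param ema EMA table (one row per scheduled prompt, answered or not).
#' @param coverage per-day coverage table from [daily_coverage()].
#' @param n_participants,n_days study dimensions defining the expected wear
#'   denominator.
#' @return list of class `"adherence_summary"`.
#' @export
adherence_summary <- function(ema, coverage, n_participants, n_days) {
  scheduled <- nrow(ema)
  if (scheduled == 0) stop("zero scheduled prompts", call. = FALSE)
  answered <- sum(!is.na(ema$response_time))
  sched_t <- clock_time_of(ema$study_day, ema$scheduled_time)
  latency <- diff_minutes(ema$response_time, sched_t)
  latency <- latency[!is.na(latency)]
  expected <- n_participants * n_days * 1440
  recorded <- sum(coverage$minutes_worn)
  daily <- coverage$minutes_worn
  structure(list(
    prompts_scheduled = scheduled,
    prompts_answered = answered,
    response_rate_pct = round(100 * answered / scheduled, 2),
    median_latency_min = stats::median(latency),
    latency_iqr_min = unname(stats::quantile(latency, c(0.25, 0.75))),
    expected_wear_min = expected,
    recorded_wear_min = recorded,
    recovery_rate_pct = round(100 * recorded / expected, 2),
    mean_daily_wear_min = mean(daily),
    sd_daily_wear_min = stats::sd(daily)
  ), class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("EMA response rate: %.2f%% (%d/%d)\n", x$response_rate_pct,
              x$prompts_answered, x$prompts_scheduled))
  cat(sprintf("Response latency: median %.1f (IQR %.1f-%.1f) minutes\n",
              x$median_latency_min, x$latency_iqr_min[1], x$latency_iqr_min[2]))
  cat(sprintf("Device recovery rate: %.2f%% (%s/%s minutes)\n",
              x$recovery_rate_pct, format(x$recorded_wear_min, big.mark = ","),
              format(x$expected_wear_min, big.mark = ",")))
  cat(sprintf("Mean daily wear time: %.0f (SD %.0f) minutes\n",
              x$mean_daily_wear_min, x$sd_daily_wear_min))
  invisible(x)
}

#' Write the run report
#'
#' Renders the analysis outputs as `report.md` (human-readable, shaped like
#' a Results section: adherence, quartile comparison table, ICCs, and the
#' three model tables) plus `report.json` with the same content as data.
#'
#' @param adherence [adherence_summary()] result.
#' @param comparisons [run_quartile_analysis()] table.
#' @param iccs list of [icc_unconditional()] results.
#' @param models list of model results from [build_table_models()].
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(adherence, comparisons, iccs, models, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Run report", "", "## Adherence", "",
          sprintf("- EMA response rate: %.2f%% (%d/%d)",
                  adherence$response_rate_pct, adherence$prompts_answered,
                  adherence$prompts_scheduled),
          sprintf("- Response latency: median %.1f (IQR %.1f-%.1f) min",
                  adherence$median_latency_min, adherence$latency_iqr_min[1],
                  adherence$latency_iqr_min[2]),
          sprintf("- Device recovery rate: %.2f%% (%s/%s min)",
                  adherence$recovery_rate_pct,
                  format(adherence$recorded_wear_min, big.mark = ","),
                  format(adherence$expected_wear_min, big.mark = ",")),
          sprintf("- Mean daily wear: %.0f (SD %.0f) min",
                  adherence$mean_daily_wear_min, adherence$sd_daily_wear_min),
          "", "## Quartile comparisons (low vs high score group)", "")
  if (!is.null(comparisons) && nrow(comparisons)) {
    sig <- comparisons[comparisons$p_adjusted < 0.05, , drop = FALSE]
    md <- c(md,
            "| instrument | metric | median low | median high | U | Z | p raw | m | p adj | r | Hedges g |",
            "|---|---|---|---|---|---|---|---|---|---|---|",
            sprintf("| %s | %s | %.1f | %.1f | %.1f | %.2f | %.4g | %d | %.4g | %.2f | %.2f |",
                    comparisons$instrument, comparisons$metric,
                    comparisons$median_low, comparisons$median_high,
                    comparisons$u_stat, comparisons$z_stat, comparisons$p_raw,
                    comparisons$m, comparisons$p_adjusted,
                    comparisons$r_effect, comparisons$hedges_g),
            "", sprintf("Significant after Bonferroni: %d of %d comparisons%s",
                        nrow(sig), nrow(comparisons),
                        if (nrow(sig)) paste0(" (",
                          paste(sprintf("%s/%s", sig$instrument, sig$metric),
                                collapse = ", "), ")") else ""))
  } else md <- c(md, "(no comparisons computed)")
  md <- c(md, "", "## Intraclass correlation coefficients", "",
          vapply(iccs, function(ic) sprintf("- %s: %.4f", ic$outcome, ic$icc),
                 character(1)),
          "", "## Multilevel models", "")
  for (oc in names(models)) {
    fit <- models[[oc]]$fit
    fe <- fit$fixed_effects
    md <- c(md, sprintf("### %s", oc), "",
            "| Predictors | Estimates | CI | P value |", "|---|---|---|---|",
            sprintf("| %s | %.2f | %.2f to %.2f | %.3g |", fe$term, fe$estimate,
                    fe$ci_low, fe$ci_high, fe$p),
            "", sprintf("AIC %.1f; var(intercept) %.3f; var(residual) %.3f; n = %d",
                        fit$aic, fit$var_intercept, fit$var_residual, fit$n_obs), "")
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    adherence = unclass(adherence),
    comparisons = comparisons,
    icc = lapply(iccs, function(ic) ic[c("outcome", "icc")]),
    models = lapply(models, function(mres) list(
      fixed_effects = mres$fit$fixed_effects,
      var_intercept = mres$fit$var_intercept,
      var_residual = mres$fit$var_residual,
      aic = mres$fit$aic, selected = mres$selected, trace = mres$trace))),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(md_path, json_path))
}
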