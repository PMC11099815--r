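# Person-mean-centered decomposition, ICC and linear mixed models for the
# EMA outcomes, with forward stepwise AIC selection.
#
# "Interindividual" predictors are the participant's own mean entered as a
# level-2 predictor and "intraindividual" predictors the within-person
# deviations from that mean (standard person-mean centering). Outcomes and
# continuous predictors are standardized over the included observations, so
# estimates are on the unit-free scale of the printed model tables. Fixed
# effects are estimated by maximum likelihood (AIC comparability); p-values
# and 95% CIs are Wald-normal.

#' Person-mean-centered decomposition of a predictor
#'
#' Splits an observation-level predictor into a between-person component
#' (the participant's mean over nonmissing values) and a within-person
#' deviation (value minus own mean). Within components sum to zero inside
#' each participant; missing values propagate.
#'
#' @param observations observation table with `participant_id`.
#' @param predictor column name to decompose.
#' @return the table with two added columns `<predictor>_between` and
#'   `<predictor>_within`.
#' @export
decompose <- function(observations, predictor) {
  x <- observations[[predictor]]
  if (is.null(x)) stop("no such predictor: ", predictor, call. = FALSE)
  if (all(is.na(x))) stop("predictor is all-missing: ", predictor, call. = FALSE)
  pm <- stats::ave(x, observations$participant_id,
                   FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  observations[[paste0(predictor, "_between")]] <- pm
  observations[[paste0(predictor, "_within")]] <- x - pm
  observations
}

#' Standardize to z-scores
#'
#' @param values numeric vector; must have positive SD over nonmissing
#'   entries.
#' @return `(x - mean) / sd`, grand mean 0 and SD 1 over the nonmissing
#'   values.
#' @export
standardize <- function(values) {
  mu <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("cannot standardize a constant", call. = FALSE)
  (values - mu) / s
}

#' Unconditional intraclass correlation of an EMA outcome
#'
#' Fits `outcome ~ 1 + (1 | participant)` by maximum likelihood and returns
#' `ICC = var_intercept / (var_intercept + var_residual)` — the share of
#' outcome variance attributable to stable between-person differences.
#'
#' @param observations observation table.
#' @param outcome outcome column (`"energy"`, `"mood"` or `"sleepiness"`).
#' @return list `outcome`, `icc`, `var_intercept`, `var_residual`, `n_obs`,
#'   `n_participants`.
#' @export
icc_unconditional <- function(observations, outcome) {
  d <- observations[!is.na(observations[[outcome]]), ]
  if (length(unique(d$participant_id)) < 2)
    stop("need >= 2 participants", call. = FALSE)
  d$.y <- standardize(d[[outcome]])
  fit <- lme4::lmer(.y ~ 1 + (1 | participant_id), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vi <- vc$vcov[vc$grp == "participant_id"]
  vr <- vc$vcov[vc$grp == "Residual"]
  list(outcome = outcome, icc = vi / (vi + vr), var_intercept = vi,
       var_residual = vr, n_obs = nrow(d),
       n_participants = length(unique(d$participant_id)))
}

mixed_formula <- function(outcome, fixed_terms, random_slope_terms) {
  fx <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  re <- if (length(random_slope_terms))
    sprintf("(1 + %s || participant_id)", paste(random_slope_terms, collapse = " + "))
  else "(1 | participant_id)"
  stats::as.formula(paste(outcome, "~", fx, "+", re))
}

#' Fit a linear mixed model for an EMA outcome
#'
#' Random intercept per participant plus the named (uncorrelated) random
#' slopes, fitted by maximum likelihood. Non-convergence is retried with up
#' to 3 perturbed restarts and flagged, never silently ignored.
#'
#' @param observations observation table; outcome and continuous predictors
#'   should already be standardized.
#' @param outcome outcome column name.
#' @param fixed_terms character vector of fixed-effect columns.
#' @param random_slope_terms character vector of random-slope columns.
#' @return object of class `"emawear_fit"`: list with `fixed_effects`
#'   (term, estimate, ci_low, ci_high, p), `var_intercept`, `var_residual`,
#'   `slope_variances`, `aic`, `n_obs`, `n_participants`, `converged`,
#'   `formula` and the underlying `model`.
#' @export
fit_mixed <- function(observations, outcome, fixed_terms,
                      random_slope_terms = character()) {
  used <- unique(c(outcome, fixed_terms, random_slope_terms, "participant_id"))
  miss <- setdiff(used, names(observations))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- observations[stats::complete.cases(observations[used]), used, drop = FALSE]
  f <- mixed_formula(outcome, fixed_terms, random_slope_terms)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = TRUE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = d, REML = FALSE, control = ctrl)))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  tries <- 0
  while (!conv && tries < 3) {
    tries <- tries + 1
    th <- lme4::getME(fit, "theta") * stats::runif(length(lme4::getME(fit, "theta")),
                                                   0.8, 1.2)
    fit2 <- suppressWarnings(stats::update(fit, start = th))
    if (length(fit2@optinfo$conv$lme4$messages) == 0) { fit <- fit2; conv <- TRUE }
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zval <- est / se
  fe <- data.frame(term = names(est), estimate = unname(est),
                   ci_low = unname(est - 1.96 * se),
                   ci_high = unname(est + 1.96 * se),
                   p = unname(2 * stats::pnorm(-abs(zval))),
                   stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vi <- sum(vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)"])
  vr <- vc$vcov[vc$grp == "Residual"]
  slopes <- vc[vc$grp != "Residual" & vc$var1 != "(Intercept)" & is.na(vc$var2), ]
  structure(list(outcome = outcome, fixed_effects = fe,
                 var_intercept = vi, var_residual = vr,
                 slope_variances = stats::setNames(slopes$vcov, slopes$var1),
                 aic = stats::AIC(fit), n_obs = nrow(d),
                 n_participants = length(unique(d$participant_id)),
                 converged = conv, formula = f, model = fit),
            class = "emawear_fit")
}

#' @export
print.emawear_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (ML, n = %d obs, %d participants%s)\n",
              paste(trimws(deparse(x$formula)), collapse = " "), x$n_obs, x$n_participants,
              if (x$converged) "" else "; NOT CONVERGED"))
  fe <- x$fixed_effects
  fe$CI <- sprintf("%.2f to %.2f", fe$ci_low, fe$ci_high)
  print(data.frame(Predictors = fe$term, Estimates = round(fe$estimate, 2),
                   CI = fe$CI, `P value` = signif(fe$p, 2),
                   check.names = FALSE), row.names = FALSE)
  cat(sprintf("var(intercept) = %.3f, var(residual) = %.3f, AIC = %.1f\n",
              x$var_intercept, x$var_residual, x$aic))
  invisible(x)
}

#' Forward stepwise AIC selection over candidate predictors
#'
#' Starts from the model containing the control terms (always kept) and
#' repeatedly adds the candidate that most reduces the AIC, while any
#' candidate strictly reduces it. Deterministic given the data.
#'
#' @param observations observation table (standardized columns).
#' @param outcome outcome column.
#' @param control_terms always-included fixed effects.
#' @param candidate_terms candidates for selection (disjoint from controls).
#' @param random_slope_terms random-slope structure used in every fit.
#' @return list `fit` (final [fit_mixed()] result), `selected` (candidates
#'   kept, in order of entry), `trace` (data.frame step / term added / AIC).
#' @export
forward_stepwise <- function(observations, outcome, control_terms,
                             candidate_terms,
                             random_slope_terms = character()) {
  if (length(intersect(control_terms, candidate_terms)))
    stop("controls and candidates must be disjoint", call. = FALSE)
  # complete cases over everything so AIC stays comparable across steps
  used <- unique(c(outcome, control_terms, candidate_terms, random_slope_terms,
                   "participant_id"))
  d <- observations[stats::complete.cases(observations[used]), , drop = FALSE]
  current <- control_terms
  fit <- fit_mixed(d, outcome, current, random_slope_terms)
  trace <- data.frame(step = 0L, added = "(controls only)", aic = fit$aic,
                      stringsAsFactors = FALSE)
  remaining <- candidate_terms
  selected <- character()
  repeat {
    if (!length(remaining)) break
    fits <- lapply(remaining, function(tm)
      fit_mixed(d, outcome, c(current, tm), random_slope_terms))
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= fit$aic - 1e-8) break
    current <- c(current, remaining[best])
    selected <- c(selected, remaining[best])
    fit <- fits[[best]]
    trace <- rbind(trace, data.frame(step = nrow(trace), added = remaining[best],
                                     aic = fit$aic))
    remaining <- remaining[-best]
  }
  list(fit = fit, selected = selected, trace = trace)
}

# Standardize a set of columns in place (constant or all-NA columns are
# dropped from the returned name list rather than erroring).
standardize_cols <- function(d, cols) {
  kept <- character()
  for (cl in cols) {
    x <- d[[cl]]
    if (is.null(x)) next
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    d[[cl]] <- standardize(x)
    kept <- c(kept, cl)
  }
  list(data = d, kept = kept)
}

#' Fit the three printed-table models (energy, mood, sleepiness)
#'
#' Prepares the modeling table (person-mean decomposition of the nightly
#' sleep and cardiac indices, standardization of outcome and continuous
#' predictors over the included observations, gender kept 0/1, response
#' time as the standardized prompt-slot index), then runs forward stepwise
#' AIC selection for each outcome with the controls always included (age,
#' gender, response time, prior-hour METs) and the outcome's published
#' random-slope structure: response time and METs for all three outcomes,
#' plus the within-person sleep heart-rate deviation for energy, the
#' within-person midpoint deviation for mood, and the within-person
#' time-in-bed deviation for sleepiness.
#'
#' @param observations output of [build_observation_table()] including
#'   demographics.
#' @param candidates decomposed candidate stems (default: the nightly sleep
#'   indices and cardiac metrics).
#' @param stepwise if `FALSE`, fit the full candidate set without selection.
#' @return named list (energy / mood / sleepiness) of [forward_stepwise()]
#'   results, with the prepared modeling table as attribute `"model_data"`.
#' @export
build_table_models <- function(observations,
                               candidates = c("bedtime", "midpoint", "tib_min",
                                              "sleep_min", "efficiency_pct",
                                              "mean_sleep_hr", "sleep_sdnn_ms"),
                               stepwise = TRUE) {
  d <- observations
  candidates <- candidates[vapply(candidates, function(cl)
    !is.null(d[[cl]]) && !all(is.na(d[[cl]])), logical(1))]
  for (cl in candidates) d <- decompose(d, cl)
  cand_cols <- as.vector(outer(candidates, c("_between", "_within"), paste0))
  controls <- c("age", "gender", "slot", "met_sum_1h")
  controls <- controls[controls %in% names(d)]
  cont_cols <- c(setdiff(controls, "gender"), cand_cols)
  std <- standardize_cols(d, cont_cols)
  d <- std$data
  cand_cols <- intersect(cand_cols, std$kept)
  controls <- intersect(controls, c(std$kept, "gender"))

  slope_of <- list(
    energy = c("slot", "met_sum_1h", "mean_sleep_hr_within"),
    mood = c("slot", "met_sum_1h", "midpoint_within"),
    sleepiness = c("slot", "met_sum_1h", "tib_min_within"))
  out <- list()
  for (oc in c("energy", "mood", "sleepiness")) {
    di <- d
    di[[oc]] <- standardize(di[[oc]])
    slopes <- intersect(slope_of[[oc]], c(controls, cand_cols))
    if (stepwise) {
      out[[oc]] <- forward_stepwise(di, oc, controls, cand_cols, slopes)
    } else {
      fit <- fit_mixed(di, oc, c(controls, cand_cols), slopes)
      out[[oc]] <- list(fit = fit, selected = cand_cols,
                        trace = data.frame(step = 0L, added = "(all candidates)",
                                           aic = fit$aic))
    }
  }
  attr(out, "model_data") <- d
  out
}
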