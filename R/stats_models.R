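## Per-animal mixed-effects models: a linear model for the maximum nose
## distance and a logistic model for the trial outcome, both with fixed
## effects for cue, trial index and session index and a random session
## intercept, plus simulation-based parameter-recovery experiments.

#' Assemble the per-trial model table
#'
#' Joins kinematic summaries and trial outcomes into the flat table the
#' mixed models consume. Only CUE/NOCUE trials appear; excluded trials
#' (onset posture or missing video) keep their outcome but carry `NA`
#' maxima, and `trial` is the within-session index counted over all trial
#' types, BLANK included.
#'
#' @param summaries data frame from [summarize_kinematics()].
#' @param outcomes data frame from [classify_outcomes()].
#' @param session_range optional length-2 vector restricting the sessions
#'   used (e.g. `c(6, 16)` for the study's large-amplitude sessions).
#' @return data frame with `animal_id`, `session_index`, `trial`, `cue`
#'   (0/1), `max_nose_mm`, `success`, `excluded`.
#' @export
build_trial_table <- function(summaries, outcomes, session_range = NULL) {
  key_o <- paste(outcomes$session_index, outcomes$trial_index)
  key_s <- paste(summaries$session_index, summaries$trial_index)
  orphan <- setdiff(key_s, key_o)
  if (length(orphan))
    stop("join error: kinematic summaries without matching outcomes for ",
         "(session trial): ", paste(utils::head(orphan, 5), collapse = "; "),
         call. = FALSE)
  m <- match(key_o, key_s)
  excluded <- rep(FALSE, nrow(outcomes))
  max_mm <- rep(NA_real_, nrow(outcomes))
  hit <- !is.na(m)
  max_mm[hit] <- summaries$max_nose_mm[m[hit]]
  excluded[hit] <- summaries$excluded_onset[m[hit]] |
    summaries$excluded_no_video[m[hit]]
  tab <- data.frame(
    animal_id = if ("animal_id" %in% names(outcomes))
      outcomes$animal_id else "sim",
    session_index = outcomes$session_index,
    trial = outcomes$trial_index,
    cue = as.integer(outcomes$trial_type == "CUE"),
    max_nose_mm = max_mm,
    success = as.integer(outcomes$success),
    excluded = excluded,
    stringsAsFactors = FALSE)
  if (!is.null(session_range))
    tab <- tab[tab$session_index >= session_range[1] &
                 tab$session_index <= session_range[2], ]
  if (!nrow(tab))
    warning("trial table is empty (no perturbation trials in range)")
  tab
}

check_fit_inputs <- function(tab) {
  if (length(unique(tab$session_index)) < 2)
    stop("mixed-model fit needs at least 2 sessions", call. = FALSE)
  if (length(unique(tab$cue)) < 2)
    stop("mixed-model fit needs both CUE and NOCUE trials", call. = FALSE)
}

#' Linear mixed model for the maximum nose distance
#'
#' Fits `max_nose_mm ~ cue + trial + session + (1 | session)` by REML,
#' mirroring the published analysis: fixed effects for the cue indicator,
#' the within-session trial index and the session index, and a random
#' session intercept. The written model also names a random intercept for
#' trials nested within session; with one observation per trial that term
#' is confounded with the residual in a linear model, so it is off by
#' default and available via `include_trial_re` (the fit falls back, with a
#' warning, when its variance collapses to the boundary). P-values are
#' Satterthwaite t-tests.
#'
#' @param table data frame from [build_trial_table()]; rows with `NA` or
#'   excluded maxima are dropped.
#' @param include_trial_re also include the observation-level
#'   (trial-within-session) random intercept.
#' @return an object of class `perch_fit` with a `coefficients` table
#'   (estimate, SE, df, statistic, p), random-effect variances and the
#'   underlying `lmerMod`.
#' @export
fit_lmm <- function(table, include_trial_re = FALSE) {
  d <- table[!table$excluded & !is.na(table$max_nose_mm), ]
  check_fit_inputs(d)
  d$session_f <- factor(d$session_index)
  d$obs_f <- factor(seq_len(nrow(d)))
  d$session <- d$session_index
  form <- max_nose_mm ~ cue + trial + session + (1 | session_f)
  if (include_trial_re) {
    form <- stats::update(form, . ~ . + (1 | obs_f))
    fit <- try(suppressMessages(
      lmerTest::lmer(form, data = d, REML = TRUE)), silent = TRUE)
    singular <- inherits(fit, "try-error") || lme4::isSingular(fit)
    if (singular) {
      warning("trial-within-session random intercept is not identifiable ",
              "from one observation per trial; refitting without it")
      return(fit_lmm(table, include_trial_re = FALSE))
    }
  } else {
    fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  }
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], df = sm[, "df"],
                   statistic = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = "linear", coefficients = co, varcor = vc,
                 n_obs = nrow(d), fit = fit,
                 include_trial_re = include_trial_re),
            class = "perch_fit")
}

#' Logistic mixed model for the trial outcome
#'
#' Fits `success ~ cue + trial + session + (1 | session)` by Laplace
#' approximation (binomial family), reporting Wald z tests and
#' exponentiated coefficients (odds ratios) with Wald 95% confidence
#' intervals. The observation-level random intercept of the written model
#' is available via `include_trial_re` (meaningful for a binary response,
#' but off by default).
#'
#' @param table data frame from [build_trial_table()].
#' @param include_trial_re include the observation-level random intercept.
#' @param ci_level confidence level for the odds-ratio interval.
#' @return a `perch_fit`; its `coefficients` table carries
#'   `exp_estimate`, `exp_lo`, `exp_hi` columns.
#' @export
fit_logistic_mm <- function(table, include_trial_re = FALSE,
                            ci_level = 0.95) {
  d <- table
  check_fit_inputs(d)
  if (all(d$success == d$success[1]))
    stop("outcome is constant; the logistic model is not estimable",
         call. = FALSE)
  d$session_f <- factor(d$session_index)
  d$obs_f <- factor(seq_len(nrow(d)))
  d$session <- d$session_index
  form <- success ~ cue + trial + session + (1 | session_f)
  if (include_trial_re) form <- stats::update(form, . ~ . + (1 | obs_f))
  fit <- suppressMessages(lme4::glmer(
    form, data = d, family = stats::binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 optCtrl = list(maxfun = 1e5))))
  est <- lme4::fixef(fit)
  if (any(abs(est) > 15))
    stop("apparent complete separation (|coefficient| > 15); consider a ",
         "penalized fit or pooling sessions", call. = FALSE)
  sm <- stats::coef(summary(fit))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  co <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], statistic = sm[, "z value"],
                   p = sm[, "Pr(>|z|)"],
                   exp_estimate = exp(sm[, "Estimate"]),
                   exp_lo = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                   exp_hi = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(model = "logistic", coefficients = co,
                 varcor = as.data.frame(lme4::VarCorr(fit)),
                 n_obs = nrow(d), fit = fit,
                 include_trial_re = include_trial_re),
            class = "perch_fit")
}

#' @export
print.perch_fit <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Render a fit as a coefficient table
#'
#' Text layout mirrors the study's tables: parameter, coefficient, standard
#' error and p-value for the linear model; parameter, exponentiated
#' coefficient, 95% CI and p-value for the logistic model. Significant
#' rows (p < 0.05) are starred. `style = "csv"` returns (and optionally
#' writes) the full machine-readable coefficient table.
#'
#' @param fit a `perch_fit`.
#' @param style `"text"` or `"csv"`.
#' @param file optional path for `style = "csv"`.
#' @return character vector of lines (`"text"`), or the coefficient data
#'   frame (`"csv"`).
#' @export
report <- function(fit, style = c("text", "csv"), file = NULL) {
  style <- match.arg(style)
  co <- fit$coefficients
  if (style == "csv") {
    if (!is.null(file)) utils::write.csv(co, file, row.names = FALSE)
    return(invisible(co))
  }
  greek <- c("(Intercept)" = "b0", cue = "b_cue", trial = "b_trial",
             session = "b_session")
  nm <- ifelse(co$term %in% names(greek), greek[co$term], co$term)
  star <- ifelse(co$p < 0.05, "*", "")
  if (fit$model == "linear") {
    lines <- c(sprintf("Linear mixed-effects model (n = %d)", fit$n_obs),
               sprintf("%-10s %12s %16s %10s", "Parameter", "Coefficient",
                       "Standard error", "p-value"),
               sprintf("%-10s %12.3g %16.3g %9.3g%s", nm, co$estimate,
                       co$se, co$p, star))
  } else {
    ci <- sprintf("%.3g-%.3g", co$exp_lo, co$exp_hi)
    lines <- c(sprintf("Logistic mixed-effects model (n = %d)", fit$n_obs),
               sprintf("%-10s %14s %16s %10s", "Parameter",
                       "Exp(coefficient)", "95% CI", "p-value"),
               sprintf("%-10s %14.3g %16s %9.3g%s", nm, co$exp_estimate,
                       ci, co$p, star))
  }
  lines
}

## ---- direct generative route for recovery experiments ---------------------

#' Simulate a model table directly from the agent's pause law
#'
#' Vectorized generation of the per-trial table without running the event
#' engine: trial types are independent draws, the perturbation-induced
#' pause is lognormal with the agent's cue/session/trial effects, success
#' is `pause < grace_ms` (the lick-grace threshold semantics of the task),
#' and the maximum nose distance follows the agent's linear amplitude
#' model plus a session random intercept and trial noise. This is the
#' well-posed generative route for parameter-recovery experiments; the
#' event engine reproduces the same laws trial by trial. Draws from the
#' calling RNG state.
#'
#' @param params a [mouse_agent()].
#' @param n_sessions,trials_per_session design size.
#' @param config a [task_config()] (trial-type probabilities, lick grace).
#' @param lin_session_re_sd SD of the session random intercept added to
#'   the linear (nose-distance) response, mm.
#' @param animal_id identifier.
#' @return a table as from [build_trial_table()].
#' @export
simulate_trial_table <- function(params, n_sessions = 11,
                                 trials_per_session = 83,
                                 config = task_config(),
                                 lin_session_re_sd = 3,
                                 animal_id = "sim") {
  rows <- lapply(seq_len(n_sessions), function(s) {
    u <- stats::runif(trials_per_session)
    type <- ifelse(u < config$p_cue, "CUE",
                   ifelse(u < config$p_cue + config$p_nocue, "NOCUE",
                          "BLANK"))
    trial <- seq_len(trials_per_session)
    keep <- type != "BLANK"
    pause <- sample_pause(type[keep], s, trial[keep], params)
    cue <- as.integer(type[keep] == "CUE")
    amp_mean <- params$response_amp_mm - params$amp_cue_mm * cue -
      params$amp_session_mm * (s - 1) +
      params$amp_trial_mm * (trial[keep] - 1)
    u_s <- stats::rnorm(1, 0, lin_session_re_sd)
    amp <- pmax(0, stats::rnorm(sum(keep), amp_mean + u_s,
                                params$response_amp_sd_mm))
    data.frame(animal_id = animal_id, session_index = s,
               trial = trial[keep], cue = cue, max_nose_mm = amp,
               success = as.integer(pause < config$lick_grace_ms),
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' True coefficients implied by the generative parameters
#'
#' For the linear model the agent's amplitude law is itself linear, so the
#' implied fixed effects are exact for any parameter values. For the
#' logistic model the pause-threshold mechanism gives exact success
#' probabilities (and hence an exact cue odds ratio) when the session and
#' trial effects on the pause are zero; non-zero values make the logistic
#' coefficients only approximate, so `implied_logistic_truth` requires the
#' null case.
#'
#' @param params a [mouse_agent()].
#' @param grace_ms lick-grace threshold, ms.
#' @return named vector of true values for `(Intercept)`, `cue`, `trial`,
#'   `session`.
#' @export
implied_linear_truth <- function(params) {
  c("(Intercept)" = params$response_amp_mm + params$amp_session_mm -
      params$amp_trial_mm,
    cue = -params$amp_cue_mm,
    trial = params$amp_trial_mm,
    session = -params$amp_session_mm)
}

#' @rdname implied_linear_truth
#' @export
implied_logistic_truth <- function(params, grace_ms = 600) {
  if (params$session_effect != 0 || params$trial_effect != 0)
    stop("implied logistic truth is exact only when session_effect and ",
         "trial_effect are 0", call. = FALSE)
  p0 <- stats::pnorm((log(grace_ms) - params$pause_mu_log) /
                       params$pause_sigma_log)
  p1 <- stats::pnorm((log(grace_ms) - params$pause_mu_log +
                        params$cue_effect) / params$pause_sigma_log)
  c("(Intercept)" = stats::qlogis(p0), cue = stats::qlogis(p1) -
      stats::qlogis(p0), trial = 0, session = 0)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` datasets from known agent parameters, fits the
#' requested mixed model to each, and tabulates bias, RMSE, Wald/profile
#' confidence-interval coverage and the rejection rate (p < 0.05) per
#' fixed effect. With all true effects zero the rejection rate is the
#' empirical type-I error and should sit near 5%; with non-zero effects
#' coverage should sit near the nominal 95%.
#'
#' @param true_params a [mouse_agent()] holding the generative truth.
#' @param n_replicates number of simulated datasets.
#' @param seed master seed (one substream per replicate).
#' @param model `"logistic"` or `"linear"`.
#' @param n_sessions,trials_per_session design size per dataset.
#' @param config a [task_config()].
#' @param lin_session_re_sd see [simulate_trial_table()].
#' @param level confidence level scored for coverage.
#' @return an object of class `perch_recovery`: per-term summary table
#'   plus the raw per-replicate estimates.
#' @export
recovery_experiment <- function(true_params, n_replicates = 200, seed = 1L,
                                model = c("logistic", "linear"),
                                n_sessions = 11, trials_per_session = 83,
                                config = task_config(),
                                lin_session_re_sd = 3, level = 0.95) {
  model <- match.arg(model)
  truth <- if (model == "logistic")
    implied_logistic_truth(true_params, config$lick_grace_ms)
  else implied_linear_truth(true_params)
  rs <- rng_streams(seed, "recovery")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ests <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    tab <- with_stream(rs, "recovery",
      simulate_trial_table(true_params, n_sessions, trials_per_session,
                           config, lin_session_re_sd))
    fit <- suppressWarnings(
      if (model == "logistic") fit_logistic_mm(tab) else fit_lmm(tab))
    co <- fit$coefficients
    co$replicate <- r
    co$lo <- co$estimate - z * co$se
    co$hi <- co$estimate + z * co$se
    ests[[r]] <- co[, c("replicate", "term", "estimate", "se", "p",
                        "lo", "hi")]
  }
  est <- do.call(rbind, ests)
  summ <- do.call(rbind, lapply(split(est, est$term), function(d) {
    tv <- truth[[d$term[1]]]
    data.frame(term = d$term[1], true = tv,
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate) - tv,
               rmse = sqrt(mean((d$estimate - tv)^2)),
               mean_se = mean(d$se),
               coverage = mean(d$lo <= tv & tv <= d$hi),
               reject_rate = mean(d$p < 0.05),
               n_replicates = n_replicates,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(model = model, summary = summ, estimates = est,
                 truth = truth, seed = seed),
            class = "perch_recovery")
}

#' @export
print.perch_recovery <- function(x, ...) {
  cat(sprintf("<perch_recovery> %s model, %d replicates\n", x$model,
              x$summary$n_replicates[1]))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Read a deposited per-animal trial table
#'
#' Import point for the published dataset benchmarks: expects a flat CSV
#' with columns `animal_id`, `session_index`, `trial`, `cue`,
#' `max_nose_mm`, `success` (and optionally `excluded`), i.e. the
#' [build_trial_table()] schema, as exported from the archived deposit.
#'
#' @param path CSV file path.
#' @return a trial table suitable for [fit_lmm()] / [fit_logistic_mm()].
#' @export
load_dryad_trials <- function(path) {
  if (!file.exists(path))
    stop("deposited trial table not found: ", path,
         "\nDownload the archived dataset and export its per-trial table ",
         "to this CSV schema (see ?load_dryad_trials).", call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "session_index", "trial", "cue", "max_nose_mm",
            "success")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("deposited table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"excluded" %in% names(d)) d$excluded <- FALSE
  d
}
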