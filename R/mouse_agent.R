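#' Virtual mouse parameters
#'
#' The stochastic agent that drives the simulator: a gamma-renewal lick
#' train at roughly 7 Hz, a lognormal perturbation-induced lick pause whose
#' location depends on the cue, the session and the trial, and a synthetic
#' nose-to-spout distance response with 50-100 ms latency, a peak near the
#' end of the 200-ms perturbation, and exponential recovery that is slower
#' than the rise.
#'
#' The pause is the behavioral bottleneck: the trial survives the
#' perturbation only if the agent resumes licking within the 600-ms
#' lick-grace window, which maps the lognormal pause onto a binary success
#' through a threshold — the construction that makes logistic
#' parameter-recovery experiments well-posed (see
#' [calibrate_cue_effect()]).
#'
#' Effect magnitudes are free simulation parameters. Defaults are chosen to
#' emulate the study conditions: ~150-ms inter-lick intervals, initiation
#' times that lengthen over a session (declining engagement), response
#' amplitudes of a few tens of mm that are smaller on cued trials and
#' shrink across sessions.
#'
#' @param interlick_mean_ms mean inter-lick interval of the gamma renewal
#'   process, ms.
#' @param interlick_shape gamma shape (regularity) of inter-lick intervals.
#' @param pause_mu_log location (log-ms) of the lognormal post-perturbation
#'   lick pause for a NOCUE trial in session 1, trial 1.
#' @param pause_sigma_log scale (log-ms) of the pause.
#' @param cue_effect reduction of `pause_mu_log` on CUE trials (>= 0).
#' @param session_effect reduction of `pause_mu_log` per session increment.
#' @param trial_effect reduction of `pause_mu_log` per trial increment
#'   (negative values lengthen pauses late in a session — fatigue).
#' @param init_latency_ms mean latency from LED on to the initiating lick.
#' @param init_latency_shape gamma shape of the initiation latency.
#' @param engagement_decay increase of the mean initiation latency per
#'   trial, ms (declining engagement).
#' @param iti_lick_rate_hz rate of stray licks during the inter-trial
#'   interval (each restarts the 5-s no-lick gate).
#' @param response_amp_mm mean peak of the nose-distance response
#'   (baseline-referenced, mm) for a NOCUE trial in session 1, trial 1.
#' @param response_amp_sd_mm between-trial SD of the peak.
#' @param amp_cue_mm reduction of the mean peak on CUE trials, mm.
#' @param amp_session_mm reduction of the mean peak per session, mm.
#' @param amp_trial_mm change of the mean peak per trial within a session,
#'   mm (positive = larger responses late in a session).
#' @param response_delay_ms length-2 range of the response latency, ms.
#' @param recovery_tau_ms exponential recovery time constant, ms.
#' @param noise_sd_mm per-frame noise SD of the synthetic trace, mm.
#' @param baseline_mm nose-to-spout distance during quiet standing, mm.
#' @param low_lik_frac fraction of frames given tracking likelihood < 0.9
#'   (and displaced coordinates) to exercise the flagging path.
#' @param anticipatory_crouch_mm optional pre-perturbation crouch amplitude
#'   on CUE trials (off by default).
#' @return an object of class `c("mouse_agent", "perch_agent")`.
#' @export
mouse_agent <- function(interlick_mean_ms = 150,
                        interlick_shape = 10,
                        pause_mu_log = log(500),
                        pause_sigma_log = 0.85,
                        cue_effect = 0.35,
                        session_effect = 0.06,
                        trial_effect = -0.003,
                        init_latency_ms = 1500,
                        init_latency_shape = 4,
                        engagement_decay = 15,
                        iti_lick_rate_hz = 0.1,
                        response_amp_mm = 52,
                        response_amp_sd_mm = 8,
                        amp_cue_mm = 6.5,
                        amp_session_mm = 2.5,
                        amp_trial_mm = 0.12,
                        response_delay_ms = c(50, 100),
                        recovery_tau_ms = 350,
                        noise_sd_mm = 1.0,
                        baseline_mm = 18,
                        low_lik_frac = 0.01,
                        anticipatory_crouch_mm = 0) {
  p <- as.list(environment())
  stopifnot(p$interlick_mean_ms > 0, p$interlick_shape > 0,
            p$pause_sigma_log > 0, p$cue_effect >= 0,
            p$init_latency_ms > 0, p$response_amp_sd_mm >= 0,
            length(p$response_delay_ms) == 2,
            all(p$response_delay_ms >= 0),
            diff(p$response_delay_ms) >= 0,
            p$recovery_tau_ms > 0, p$noise_sd_mm >= 0,
            p$low_lik_frac >= 0, p$low_lik_frac <= 1)
  structure(p, class = c("mouse_agent", "perch_agent"))
}

#' Deterministic scripted agent
#'
#' A metronome mouse for oracle tests and acceptance checks: licks at a
#' fixed cadence, optionally stops licking mid-trial on every `abort_every`-th
#' trial (forcing an abort 600 ms after its last lick), and produces no
#' pose output. `lick_interval_ms = NA` gives an agent that never licks.
#'
#' @param lick_interval_ms fixed inter-lick interval, ms (`NA` = no licks).
#' @param init_latency_ms fixed latency from LED on to the first lick.
#' @param abort_every stop licking on every k-th trial (`NA` = never).
#' @param abort_at_ms time after trial start at which the scripted abort
#'   stops the lick train.
#' @return an object of class `c("scripted_agent", "perch_agent")`.
#' @export
scripted_agent <- function(lick_interval_ms = 150, init_latency_ms = 500,
                           abort_every = NA, abort_at_ms = 3000) {
  structure(list(lick_interval_ms = lick_interval_ms,
                 init_latency_ms = init_latency_ms,
                 abort_every = abort_every, abort_at_ms = abort_at_ms),
            class = c("scripted_agent", "perch_agent"))
}

## ---- agent interface ------------------------------------------------------

#' Agent interface generics
#'
#' The task engine talks to agents through four generics:
#' `agent_init_latency` (latency from LED on to the initiating lick, ms;
#' `Inf` means the agent does not start a trial), `agent_iti_gap` (gap to
#' the next stray inter-trial lick, ms; `Inf` = none), `agent_trial_licks`
#' (the lick train of one trial, starting at the initiating lick), and
#' [generate_pose_track()]. All draw from the calling RNG state.
#'
#' @param agent a `perch_agent`.
#' @param trial_number 1-based trial counter within the session.
#' @name agent-interface
NULL

#' @rdname agent-interface
#' @export
agent_init_latency <- function(agent, trial_number)
  UseMethod("agent_init_latency")

#' @export
agent_init_latency.mouse_agent <- function(agent, trial_number) {
  m <- agent$init_latency_ms + agent$engagement_decay * (trial_number - 1)
  max(1, round(stats::rgamma(1, shape = agent$init_latency_shape,
                             rate = agent$init_latency_shape / m)))
}

#' @export
agent_init_latency.scripted_agent <- function(agent, trial_number) {
  if (is.na(agent$lick_interval_ms)) Inf else agent$init_latency_ms
}

#' @rdname agent-interface
#' @param trial_type,session_index trial context for the pause draw.
#' @export
agent_pause <- function(agent, trial_type, session_index, trial_number)
  UseMethod("agent_pause")

#' @export
agent_pause.mouse_agent <- function(agent, trial_type, session_index,
                                    trial_number)
  sample_pause(trial_type, session_index, trial_number, agent)

#' @export
agent_pause.scripted_agent <- function(agent, trial_type, session_index,
                                       trial_number) 0

#' @rdname agent-interface
#' @export
agent_iti_gap <- function(agent) UseMethod("agent_iti_gap")

#' @export
agent_iti_gap.mouse_agent <- function(agent) {
  if (agent$iti_lick_rate_hz <= 0) return(Inf)
  max(1, round(1000 * stats::rexp(1, agent$iti_lick_rate_hz)))
}

#' @export
agent_iti_gap.scripted_agent <- function(agent) Inf

#' @rdname agent-interface
#' @param first_lick_ms time of the initiating lick (ms).
#' @param horizon_ms generate licks up to at least this time.
#' @param pause_start_ms perturbation onset starting the lick pause
#'   (`NA` = no perturbation scheduled).
#' @param pause_ms pause duration from [sample_pause()].
#' @export
agent_trial_licks <- function(agent, first_lick_ms, horizon_ms,
                              pause_start_ms = NA, pause_ms = 0,
                              trial_number = 1)
  UseMethod("agent_trial_licks")

#' @export
agent_trial_licks.mouse_agent <- function(agent, first_lick_ms, horizon_ms,
                                          pause_start_ms = NA, pause_ms = 0,
                                          trial_number = 1) {
  shape <- agent$interlick_shape
  rate <- shape / agent$interlick_mean_ms
  t <- first_lick_ms
  licks <- t
  paused <- is.na(pause_start_ms)
  while (t < horizon_ms) {
    tn <- t + max(1, round(stats::rgamma(1, shape = shape, rate = rate)))
    if (!paused && tn > pause_start_ms) {
      # perturbation interrupts licking; resume once the pause elapses
      tn <- max(tn, pause_start_ms + round(pause_ms))
      paused <- TRUE
    }
    licks <- c(licks, tn)
    t <- tn
  }
  licks
}

#' @export
agent_trial_licks.scripted_agent <- function(agent, first_lick_ms,
                                             horizon_ms, pause_start_ms = NA,
                                             pause_ms = 0, trial_number = 1) {
  if (is.na(agent$lick_interval_ms)) return(numeric(0))
  licks <- seq(first_lick_ms, horizon_ms + agent$lick_interval_ms,
               by = agent$lick_interval_ms)
  if (!is.na(agent$abort_every) &&
      trial_number %% agent$abort_every == 0)
    licks <- licks[licks <= first_lick_ms + agent$abort_at_ms]
  licks
}

## ---- pause model ----------------------------------------------------------

#' Sample the perturbation-induced lick pause
#'
#' Lognormal pause (ms) with additive effects on the log scale:
#' `mu = pause_mu_log - cue_effect * is_cue - session_effect * (session - 1)
#' - trial_effect * (trial - 1)`. BLANK trials have no perturbation and no
#' pause (returns 0). Vectorized over `trial_type`, `session_index` and
#' `trial_index`; draws from the calling RNG state.
#'
#' @param trial_type `"CUE"`, `"NOCUE"` or `"BLANK"` (vectorized).
#' @param session_index,trial_index 1-based indices.
#' @param params a [mouse_agent()].
#' @return pause duration(s), ms.
#' @export
sample_pause <- function(trial_type, session_index, trial_index, params) {
  n <- max(length(trial_type), length(session_index), length(trial_index))
  trial_type <- rep_len(as.character(trial_type), n)
  session_index <- rep_len(session_index, n)
  trial_index <- rep_len(trial_index, n)
  mu <- params$pause_mu_log -
    params$cue_effect * (trial_type == "CUE") -
    params$session_effect * (session_index - 1) -
    params$trial_effect * (trial_index - 1)
  out <- stats::rlnorm(n, meanlog = mu, sdlog = params$pause_sigma_log)
  out[trial_type == "BLANK"] <- 0
  out
}

#' Calibrate the cue effect to a target success odds ratio
#'
#' With pause `~ LogNormal(mu, sigma)` and success defined by
#' `pause < grace`, the NOCUE success probability is
#' `p0 = pnorm((log(grace) - mu) / sigma)`. The cue effect `delta` that
#' yields a target odds ratio `OR` satisfies
#' `qnorm(p1) = qnorm(p0) + delta / sigma` with
#' `odds(p1) = OR * odds(p0)`, giving the closed form
#' `delta = sigma * (qnorm(p1) - qnorm(p0))`.
#'
#' @param target_or desired success odds ratio of CUE over NOCUE.
#' @param params a [mouse_agent()] providing `pause_mu_log` and
#'   `pause_sigma_log`.
#' @param grace_ms the lick-grace threshold, ms.
#' @return the `cue_effect` value (reduction of `pause_mu_log`).
#' @export
calibrate_cue_effect <- function(target_or, params, grace_ms = 600) {
  p0 <- stats::pnorm((log(grace_ms) - params$pause_mu_log) /
                       params$pause_sigma_log)
  odds1 <- target_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  params$pause_sigma_log * (stats::qnorm(p1) - stats::qnorm(p0))
}

## ---- synthetic pose tracks ------------------------------------------------

#' Generate a synthetic pose track for one trial
#'
#' 200-fps nose and spout coordinates covering the trial plus 3 s on each
#' side, in the single-animal pose-estimation CSV geometry (x, y and a
#' likelihood per bodypart). The nose-to-spout distance is a constant
#' baseline plus white noise; if the trial's perturbation was delivered the
#' distance rises after a latency drawn uniformly from
#' `response_delay_ms` (50-100 ms), peaks at the end of the 200-ms platform
#' movement (half-cosine rise), and decays exponentially with
#' `recovery_tau_ms`, making the descending slope shallower than the
#' ascending one. BLANK and undelivered-perturbation trials stay at
#' baseline. A fraction `low_lik_frac` of frames get likelihood < 0.9 and
#' displaced nose coordinates to exercise the tracking-quality flagging
#' path. Draws from the calling RNG state.
#'
#' @param trial one trial record row (needs `start_ms`, `end_ms`,
#'   `trial_type`, `pert_onset_ms`, `pert_offset_ms`, and indices).
#' @param params a [mouse_agent()].
#' @param scale a [calibration_scale()] mapping mm to px.
#' @param pad_ms padding before/after the trial, ms.
#' @return a `pose_track` data frame (`frame`, `t_ms`, `nose_x`, `nose_y`,
#'   `nose_likelihood`, `spout_x`, `spout_y`, `spout_likelihood`) with the
#'   drawn `response_amp_mm` and `response_delay_ms` as attributes.
#' @export
generate_pose_track <- function(trial, params,
                                scale = calibration_scale(),
                                pad_ms = 3000) {
  t0 <- max(0, trial$start_ms - pad_ms)
  t1 <- trial$end_ms + pad_ms
  t <- seq(t0, t1, by = 5)  # 200 fps
  n <- length(t)

  delivered <- !is.na(trial$pert_onset_ms)
  amp <- NA_real_
  delay <- NA_real_
  resp <- numeric(n)
  if (delivered) {
    delay <- round(stats::runif(1, params$response_delay_ms[1],
                                params$response_delay_ms[2]))
    amp_mean <- params$response_amp_mm -
      params$amp_cue_mm * (trial$trial_type == "CUE") -
      params$amp_session_mm * (trial$session_index - 1) +
      params$amp_trial_mm * (trial$trial_index - 1)
    amp <- max(0, stats::rnorm(1, amp_mean, params$response_amp_sd_mm))
    onset <- trial$pert_onset_ms + delay
    peak <- trial$pert_offset_ms
    rise <- t >= onset & t <= peak
    resp[rise] <- amp * (1 - cos(pi * (t[rise] - onset) /
                                   max(peak - onset, 1))) / 2
    fall <- t > peak
    resp[fall] <- amp * exp(-(t[fall] - peak) / params$recovery_tau_ms)
  }
  crouch <- numeric(n)
  if (params$anticipatory_crouch_mm > 0 && !is.na(trial$cue_on_ms)) {
    pre <- t >= trial$cue_on_ms &
      t <= (if (delivered) trial$pert_onset_ms else trial$end_ms)
    crouch[pre] <- -params$anticipatory_crouch_mm
  }

  dist_mm <- params$baseline_mm + resp + crouch +
    stats::rnorm(n, 0, params$noise_sd_mm)
  dist_px <- pmax(0, dist_mm) / scale$mm_per_px

  spout <- c(x = 420, y = 160)
  u <- c(-0.8, 0.6)  # unit vector from spout towards the nose
  nose_x <- spout[["x"]] + u[1] * dist_px + stats::rnorm(n, 0, 0.5)
  nose_y <- spout[["y"]] + u[2] * dist_px + stats::rnorm(n, 0, 0.5)
  lik <- 0.95 + 0.05 * stats::runif(n)
  n_bad <- stats::rbinom(1, n, params$low_lik_frac)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    lik[bad] <- stats::runif(n_bad, 0.05, 0.89)
    nose_x[bad] <- nose_x[bad] + stats::rnorm(n_bad, 0, 40)
    nose_y[bad] <- nose_y[bad] + stats::rnorm(n_bad, 0, 40)
  }

  out <- data.frame(frame = seq_len(n) - 1L, t_ms = t,
                    nose_x = nose_x, nose_y = nose_y, nose_likelihood = lik,
                    spout_x = spout[["x"]] + stats::rnorm(n, 0, 0.3),
                    spout_y = spout[["y"]] + stats::rnorm(n, 0, 0.3),
                    spout_likelihood = 0.99 + 0.01 * stats::runif(n))
  class(out) <- c("pose_track", "data.frame")
  attr(out, "fps") <- 200
  attr(out, "response_amp_mm") <- amp
  attr(out, "response_delay_ms") <- delay
  attr(out, "trial_index") <- trial$trial_index
  out
}

## ---- dataset generation ---------------------------------------------------

#' Simulate a multi-session dataset
#'
#' Runs [run_session()] for `n_sessions` sessions with per-session seeds
#' derived from `seed`, optionally writing one event log (ndjson) and one
#' pose CSV per session plus combined `trials.csv` and `truth.csv` tables
#' to `out_dir`. The truth table records every latent agent draw (pause
#' durations, response amplitudes, delivery and success flags) for oracle
#' tests against the analysis pipeline.
#'
#' @param config a [task_config()].
#' @param agent a `perch_agent`.
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param seed integer master seed.
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @param poses generate pose tracks (needed for kinematic analysis).
#' @param animal_id identifier used in all records.
#' @return an object of class `perch_dataset`: list of `perch_session`s
#'   plus combined `trials` and `truth` tables.
#' @export
simulate_dataset <- function(config, agent, n_sessions = 11,
                             trials_per_session = config$max_trials,
                             seed = 1L, out_dir = NULL, poses = TRUE,
                             animal_id = "sim") {
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    seed_s <- (abs(as.double(seed)) * 131071 + s * 524287) %% 2147483629
    sessions[[s]] <- run_session(config, agent, seed = seed_s,
                                 n_trials = trials_per_session,
                                 session_index = s, poses = poses,
                                 animal_id = animal_id)
  }
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  truth <- do.call(rbind, lapply(sessions, `[[`, "truth"))
  ds <- structure(list(sessions = sessions, trials = trials, truth = truth,
                       config = config, agent = agent, seed = seed,
                       animal_id = animal_id),
                  class = "perch_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' @export
print.perch_dataset <- function(x, ...) {
  cat(sprintf("<perch_dataset> %s: %d sessions x %d trials, seed %s\n",
              x$animal_id, length(x$sessions),
              nrow(x$sessions[[1]]$trials), format(x$seed)))
  invisible(x)
}
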