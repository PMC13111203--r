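## Event-driven implementation of the task state machine.
##
## Times are session-relative integer milliseconds (the rig's 1-ms tick).
## Three states: INTERTRIAL (LED off, licks unrewarded, no-lick gate),
## READY (LED on, waiting for the initiating lick), ACTIVE (trial running).

EVENT_KINDS <- c("LED_ON", "LED_OFF", "LICK", "REWARD", "CUE_ON", "CUE_OFF",
                 "PERT_ON", "PERT_OFF", "TRIAL_START", "TRIAL_END", "FRAME")

#' Sample the type of the next trial
#'
#' Trial types are CUE (perturbation preceded by a 1-s tone), NOCUE
#' (perturbation, no tone) and BLANK (neither), drawn independently with
#' probabilities `p_cue`/`p_nocue`/`p_blank` (0.74/0.13/0.13 by default) —
#' except that a trial aborted before its stimulus is repeated: a CUE trial
#' aborted before its scheduled cue onset, or a NOCUE/BLANK trial aborted
#' before its scheduled (for BLANK, virtual) perturbation onset, forces the
#' next trial to the same type.
#'
#' Draws from the calling RNG state.
#'
#' @param config a [task_config()].
#' @param previous the previous trial's record (a one-row data frame or
#'   list with `trial_type`, `completion`, `end_ms`, `cue_on_sched_ms`,
#'   `pert_sched_ms`), or `NULL` for the first trial.
#' @return one of `"CUE"`, `"NOCUE"`, `"BLANK"`.
#' @export
sample_trial_type <- function(config, previous = NULL) {
  if (!is.null(previous) && repeat_trial_type(previous))
    return(as.character(previous$trial_type))
  u <- stats::runif(1)
  if (u < config$p_cue) "CUE"
  else if (u < config$p_cue + config$p_nocue) "NOCUE"
  else "BLANK"
}

# TRUE when the repetition rule applies: aborted before the trial's stimulus
# (the cue for CUE trials, the scheduled/virtual perturbation otherwise).
repeat_trial_type <- function(previous) {
  if (as.character(previous$completion) != "aborted") return(FALSE)
  ref <- if (as.character(previous$trial_type) == "CUE")
    previous$cue_on_sched_ms else previous$pert_sched_ms
  isTRUE(previous$end_ms <= ref)
}

#' Sample a perturbation delay
#'
#' The perturbation onset is scheduled a random delay after the trial's
#' first lick. The delay follows an exponential distribution of mean
#' `pert_delay_mean_s` (1 s) conditioned on the truncation interval
#' \[`pert_delay_lo_s`, `pert_delay_hi_s`\] (2.5-6 s), sampled by inverse
#' CDF. Draws from the calling RNG state.
#'
#' @param config a [task_config()].
#' @param n number of samples.
#' @return delay(s) in seconds, all within the truncation bounds.
#' @export
sample_perturbation_delay <- function(config, n = 1) {
  lo <- config$pert_delay_lo_s
  hi <- config$pert_delay_hi_s
  m <- config$pert_delay_mean_s
  if (lo > hi || m <= 0)
    stop("invalid delay configuration: need lo <= hi and mean > 0",
         call. = FALSE)
  if (lo == hi) return(rep(lo, n))
  u <- stats::runif(n)
  flo <- exp(-lo / m)
  fhi <- exp(-hi / m)
  -m * log(flo - u * (flo - fhi))
}

# closed-form mean of Exp(mean m) conditioned on [lo, hi]
truncated_exp_mean <- function(m, lo, hi) {
  if (lo == hi) return(lo)
  w <- (hi - lo) / m
  lo + m - (hi - lo) * exp(-w) / (1 - exp(-w))
}

#' Schedule the next inter-trial interval
#'
#' Uniform on \[`iti_lo_s`, `iti_hi_s`\] (10-15 s), plus the
#' `abort_penalty_s` time-out (20 s) when the preceding trial aborted.
#' Draws from the calling RNG state.
#'
#' @param aborted logical; did the preceding trial abort?
#' @param config a [task_config()].
#' @return interval in seconds.
#' @export
schedule_intertrial <- function(aborted, config) {
  stats::runif(1, config$iti_lo_s, config$iti_hi_s) +
    if (isTRUE(aborted)) config$abort_penalty_s else 0
}

#' Initial state of the task state machine
#'
#' @param config a [task_config()].
#' @param t0_ms session start time (ms).
#' @return a `task_state` list.
#' @export
new_task_state <- function(config, t0_ms = 0) {
  structure(list(phase = "INTERTRIAL",
                 last_lick_ms = -Inf,
                 last_reward_ms = -Inf,
                 trial_start_ms = NA_real_,
                 iti_end_ms = t0_ms,
                 led_due_ms = t0_ms),
            class = "task_state")
}

#' Advance the task state machine by one stimulus
#'
#' Pure transition function of the rig's state machine. States transition
#' either by a lick (behavioral input) or an elapsed timer (virtual input):
#'
#' * `INTERTRIAL` + lick: restarts the 5-s no-lick gate (the LED turns on
#'   at the later of the inter-trial interval end and last lick + gate).
#' * `INTERTRIAL` + `led` timer: LED on, enter `READY`.
#' * `READY` + lick: trial starts, first reward delivered immediately,
#'   enter `ACTIVE`.
#' * `ACTIVE` + lick: restarts the 600-ms lick-grace timer; delivers a
#'   reward if at least 1,100 ms (`water_timer_ms`) elapsed since the
#'   previous reward.
#' * `ACTIVE` + `lick_grace` timer: trial aborted, LED off.
#' * `ACTIVE` + `trial_max` timer: trial complete (7.5 s), LED off.
#'
#' Simultaneous stimuli are resolved trial-max timer first, then licks,
#' then the lick-grace timer, so a lick exactly at the grace deadline keeps
#' the trial alive (only lick-free periods strictly longer than 600 ms
#' abort). The water timer is not a stimulus: its condition is evaluated
#' when a lick arrives.
#'
#' @param state a `task_state` from [new_task_state()] or a previous call.
#' @param stimulus a list with `kind` (`"lick"` or `"timer"`), `t_ms`, and
#'   for timers `timer` (one of `"led"`, `"lick_grace"`, `"trial_max"`).
#' @param config a [task_config()].
#' @return list with the new `state`, `events` (data frame of emitted
#'   `t_ms`/`kind`), and `trial_end` (`NULL`, or a list with `t_ms` and
#'   `completion` when the stimulus ended a trial).
#' @export
advance <- function(state, stimulus, config) {
  t <- stimulus$t_ms
  emitted <- character(0)
  times <- numeric(0)
  emit <- function(kind, at = t) {
    emitted <<- c(emitted, kind)
    times <<- c(times, at)
  }
  trial_end <- NULL

  key <- paste(state$phase, stimulus$kind,
               if (identical(stimulus$kind, "timer")) stimulus$timer else "",
               sep = ".")
  switch(key,
    "INTERTRIAL.lick." = {
      state$last_lick_ms <- t
      state$led_due_ms <- max(state$iti_end_ms,
                              t + 1000 * config$nolick_gate_s)
      emit("LICK")
    },
    "INTERTRIAL.timer.led" = {
      state$phase <- "READY"
      emit("LED_ON")
    },
    "READY.lick." = {
      state$phase <- "ACTIVE"
      state$trial_start_ms <- t
      state$last_lick_ms <- t
      state$last_reward_ms <- t
      emit("TRIAL_START")
      emit("LICK")
      emit("REWARD")
    },
    "ACTIVE.lick." = {
      emit("LICK")
      if (t - state$last_reward_ms >= config$water_timer_ms) {
        state$last_reward_ms <- t
        emit("REWARD")
      }
      state$last_lick_ms <- t
    },
    "ACTIVE.timer.lick_grace" = {
      if (t != state$last_lick_ms + config$lick_grace_ms)
        stop("advance: lick-grace timer fired at an inconsistent time",
             call. = FALSE)
      emit("TRIAL_END")
      emit("LED_OFF")
      state$phase <- "INTERTRIAL"
      trial_end <- list(t_ms = t, completion = "aborted")
    },
    "ACTIVE.timer.trial_max" = {
      emit("TRIAL_END")
      emit("LED_OFF")
      state$phase <- "INTERTRIAL"
      trial_end <- list(t_ms = t, completion = "complete")
    },
    stop("advance: undefined transition for state '", state$phase,
         "' and stimulus '", stimulus$kind,
         if (identical(stimulus$kind, "timer"))
           paste0("/", stimulus$timer) else "",
         "'", call. = FALSE)
  )
  list(state = state,
       events = data.frame(t_ms = times, kind = emitted,
                           stringsAsFactors = FALSE),
       trial_end = trial_end)
}

# Drive one trial through `advance` given the agent's lick times.
# `licks` must start at the initiating lick and extend beyond any possible
# trial end. Returns events (t_ms, kind), end time and completion.
drive_trial <- function(state, licks, config) {
  grace <- config$lick_grace_ms
  trial_max_ms <- round(1000 * config$trial_max_s)
  out_t <- numeric(0)
  out_k <- character(0)
  li <- 1L
  trial_end <- NULL
  repeat {
    t_lick <- if (li <= length(licks)) licks[li] else Inf
    t_grace <- if (state$phase == "ACTIVE")
      state$last_lick_ms + grace else Inf
    t_max <- if (state$phase == "ACTIVE")
      state$trial_start_ms + trial_max_ms else Inf
    t_next <- min(t_lick, t_grace, t_max)
    if (!is.finite(t_next))
      stop("drive_trial: no pending stimulus", call. = FALSE)
    # tie order at equal times: trial-max timer, lick, lick-grace timer
    stim <- if (t_max <= t_next) {
      list(kind = "timer", timer = "trial_max", t_ms = t_max)
    } else if (t_lick <= t_next) {
      li <- li + 1L
      list(kind = "lick", t_ms = t_lick)
    } else {
      list(kind = "timer", timer = "lick_grace", t_ms = t_grace)
    }
    step <- advance(state, stim, config)
    state <- step$state
    out_t <- c(out_t, step$events$t_ms)
    out_k <- c(out_k, step$events$kind)
    if (!is.null(step$trial_end)) {
      trial_end <- step$trial_end
      break
    }
  }
  list(state = state,
       events = data.frame(t_ms = out_t, kind = out_k,
                           stringsAsFactors = FALSE),
       end_ms = trial_end$t_ms, completion = trial_end$completion)
}

#' Simulate one session of the task
#'
#' Runs `n_trials` trials of the closed-loop task with a virtual mouse.
#' All randomness flows from `seed` through named substreams (trial-type
#' scheduler, perturbation delay, inter-trial interval, agent), so
#' identical `(config, agent, seed)` give identical sessions.
#'
#' Per trial: the LED turns on at the later of the inter-trial interval end
#' and 5 s after the last lick; the agent's first lick starts the trial and
#' is rewarded immediately; the perturbation is scheduled at the first lick
#' plus a truncated-exponential delay (a virtual onset is drawn for BLANK
#' trials too, used only for the abort-repetition rule); in CUE trials the
#' tone starts 1 s before the perturbation and ends with the platform
#' movement. A trial that aborts before its scheduled onset receives no
#' perturbation; one that aborts during the 200-ms movement still sees the
#' platform finish (PERT_OFF can fall after TRIAL_END).
#'
#' @param config a [task_config()].
#' @param agent a [mouse_agent()] or [scripted_agent()].
#' @param seed integer master seed.
#' @param n_trials number of trials (default `config$max_trials`, the
#'   study's median 83).
#' @param session_index 1-based session number (enters the agent's
#'   session-level effects).
#' @param poses logical; also generate synthetic pose tracks (and FRAME
#'   events) for each trial.
#' @param animal_id identifier stored in the records.
#' @return an object of class `perch_session`: list with `trials` (one row
#'   per trial), `events` (the full log), `poses` (list of pose tracks or
#'   `NULL`), `truth` (latent agent draws for oracle tests), plus the
#'   inputs.
#' @examples
#' s <- run_session(task_config(), scripted_agent(), seed = 1, n_trials = 3)
#' s$trials[, c("trial_type", "completion", "n_rewards")]
#' @export
run_session <- function(config, agent, seed = 1L,
                        n_trials = config$max_trials,
                        session_index = 1L, poses = FALSE,
                        animal_id = "sim") {
  stopifnot(inherits(config, "task_config"), n_trials >= 1)
  rs <- rng_streams(seed)
  gate_ms <- round(1000 * config$nolick_gate_s)
  cue_lead_ms <- round(1000 * config$cue_lead_s)
  pert_dur_ms <- round(1000 * config$pert_duration_s)
  trial_max_ms <- round(1000 * config$trial_max_s)

  ev_t <- numeric(0); ev_k <- character(0); ev_i <- integer(0)
  add_events <- function(t, kind, trial) {
    ev_t <<- c(ev_t, t); ev_k <<- c(ev_k, kind)
    ev_i <<- c(ev_i, rep(as.integer(trial), length(t)))
  }

  state <- new_task_state(config)
  prev <- NULL
  trials <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  pose_list <- if (poses) vector("list", n_trials) else NULL

  for (i in seq_len(n_trials)) {
    type <- with_stream(rs, "trial_type", sample_trial_type(config, prev))

    if (i == 1L) {
      iti_s <- 0
      state$iti_end_ms <- 0
      iti_from <- 0
    } else {
      iti_s <- with_stream(rs, "iti",
        schedule_intertrial(prev$completion == "aborted", config))
      state$iti_end_ms <- prev$end_ms + round(1000 * iti_s)
      iti_from <- prev$end_ms
    }
    state$led_due_ms <- max(state$iti_end_ms,
                            if (is.finite(state$last_lick_ms))
                              state$last_lick_ms + gate_ms else -Inf)

    # stray licks during the inter-trial interval push the no-lick gate back
    t_cursor <- iti_from
    repeat {
      gap <- with_stream(rs, "agent", agent_iti_gap(agent))
      cand <- t_cursor + gap
      if (!is.finite(cand) || cand >= state$led_due_ms) break
      step <- advance(state, list(kind = "lick", t_ms = cand), config)
      state <- step$state
      add_events(step$events$t_ms, step$events$kind, NA)
      t_cursor <- cand
    }
    step <- advance(state,
                    list(kind = "timer", timer = "led",
                         t_ms = state$led_due_ms), config)
    state <- step$state
    led_on_ms <- state$led_due_ms
    add_events(step$events$t_ms, step$events$kind, i)

    latency <- with_stream(rs, "agent", agent_init_latency(agent, i))
    if (!is.finite(latency)) break  # agent never initiates; LED stays on
    first_lick <- led_on_ms + latency

    delay_s <- with_stream(rs, "delay", sample_perturbation_delay(config))
    pert_sched <- first_lick + round(1000 * delay_s)
    cue_sched <- pert_sched - cue_lead_ms

    pause_ms <- if (type == "BLANK") 0 else
      with_stream(rs, "agent",
                  agent_pause(agent, type, session_index, i))

    licks <- with_stream(rs, "agent",
      agent_trial_licks(agent, first_lick,
                        horizon_ms = first_lick + trial_max_ms +
                          config$lick_grace_ms + 200,
                        pause_start_ms = if (type == "BLANK") NA
                                         else pert_sched,
                        pause_ms = pause_ms, trial_number = i))

    run <- drive_trial(state, licks, config)
    state <- run$state
    add_events(run$events$t_ms, run$events$kind, i)
    end_ms <- run$end_ms

    delivered <- type != "BLANK" && end_ms > pert_sched
    pert_on <- if (delivered) pert_sched else NA_real_
    pert_off <- if (delivered) pert_sched + pert_dur_ms else NA_real_
    cue_on <- cue_off <- NA_real_
    if (type == "CUE" && end_ms > cue_sched) {
      cue_on <- cue_sched
      cue_off <- if (delivered) pert_off else end_ms
      add_events(c(cue_on, cue_off), c("CUE_ON", "CUE_OFF"), i)
    }
    if (delivered)
      add_events(c(pert_on, pert_off), c("PERT_ON", "PERT_OFF"), i)

    reward_times <- run$events$t_ms[run$events$kind == "REWARD"]
    trials[[i]] <- data.frame(
      trial_index = i, session_index = session_index, animal_id = animal_id,
      trial_type = type, start_ms = first_lick, end_ms = end_ms,
      completion = run$completion, n_rewards = length(reward_times),
      led_on_ms = led_on_ms, scheduled_iti_s = iti_s,
      pert_sched_ms = pert_sched, pert_onset_ms = pert_on,
      pert_offset_ms = pert_off, cue_on_sched_ms = cue_sched,
      cue_on_ms = cue_on, cue_off_ms = cue_off,
      stringsAsFactors = FALSE)

    truth_amp <- NA_real_; truth_delay <- NA_real_
    if (poses) {
      pt <- with_stream(rs, "agent",
        generate_pose_track(trials[[i]], agent))
      pose_list[[i]] <- pt
      truth_amp <- attr(pt, "response_amp_mm")
      truth_delay <- attr(pt, "response_delay_ms")
      add_events(pt$t_ms, rep("FRAME", nrow(pt)), i)
    }
    truth[[i]] <- data.frame(
      trial_index = i, session_index = session_index, trial_type = type,
      pause_ms = if (type == "BLANK") NA_real_ else pause_ms,
      response_amp_mm = truth_amp, response_delay_ms = truth_delay,
      delivered = delivered,
      success_truth = if (type == "BLANK") NA else
        delivered && any(reward_times > pert_off),
      stringsAsFactors = FALSE)

    prev <- trials[[i]]
  }

  ord <- order(ev_t, seq_along(ev_t))
  events <- data.frame(t_ms = ev_t[ord], kind = ev_k[ord],
                       trial_index = ev_i[ord], stringsAsFactors = FALSE)
  trials_df <- do.call(rbind, trials)
  truth_df <- do.call(rbind, truth)
  if (is.null(trials_df)) {
    trials_df <- data.frame(trial_index = integer(0),
                            session_index = integer(0),
                            animal_id = character(0),
                            trial_type = character(0), start_ms = numeric(0),
                            end_ms = numeric(0), completion = character(0),
                            n_rewards = integer(0), led_on_ms = numeric(0),
                            scheduled_iti_s = numeric(0),
                            pert_sched_ms = numeric(0),
                            pert_onset_ms = numeric(0),
                            pert_offset_ms = numeric(0),
                            cue_on_sched_ms = numeric(0),
                            cue_on_ms = numeric(0), cue_off_ms = numeric(0))
    truth_df <- data.frame(trial_index = integer(0),
                           session_index = integer(0),
                           trial_type = character(0), pause_ms = numeric(0),
                           response_amp_mm = numeric(0),
                           response_delay_ms = numeric(0),
                           delivered = logical(0), success_truth = logical(0))
  }
  structure(list(session_index = session_index, animal_id = animal_id,
                 config = config, agent = agent, seed = seed,
                 trials = trials_df, events = events,
                 poses = pose_list, truth = truth_df),
            class = "perch_session")
}

#' @export
print.perch_session <- function(x, ...) {
  n_ab <- sum(x$trials$completion == "aborted")
  cat(sprintf(paste0(
    "<perch_session> session %d (%s): %d trials (%d aborted), %d events, ",
    "seed %s\n"), x$session_index, x$animal_id, nrow(x$trials), n_ab,
    nrow(x$events), format(x$seed)))
  invisible(x)
}
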