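# Task engine: configuration, samplers, perturbation profiles, and the
# state machine driven through whole simulated sessions.

test_that("configuration invariants are enforced", {
  expect_s3_class(task_config(), "task_config")
  expect_error(task_config(p_cue = 0.8), "must equal 1")
  expect_error(task_config(p_cue = -0.1, p_nocue = 0.55, p_blank = 0.55),
               "\\[0, 1\\]")
  expect_error(task_config(pert_delay_lo_s = 7), "pert_delay_lo_s")
  expect_error(task_config(pert_delay_lo_s = 0.5), "cue_lead_s")
  expect_error(task_config(iti_lo_s = 16), "iti_lo_s")
  expect_error(task_config(lick_grace_ms = 0), "positive")
})

test_that("trial-type scheduler reproduces probabilities and repetition", {
  cfg <- task_config()
  set.seed(11)
  expect_equal(sample_trial_type(task_config(p_cue = 1, p_nocue = 0,
                                             p_blank = 0)), "CUE")

  # CUE trial aborted at 1.2 s with cue scheduled at 2.0 s is repeated
  prev <- list(trial_type = "CUE", completion = "aborted", end_ms = 1200,
               cue_on_sched_ms = 2000, pert_sched_ms = 3000)
  expect_equal(sample_trial_type(cfg, prev), "CUE")
  # aborted after the cue: no repetition forced; BLANK repeats against the
  # virtual perturbation onset
  prev_blank <- list(trial_type = "BLANK", completion = "aborted",
                     end_ms = 2500, cue_on_sched_ms = 2000,
                     pert_sched_ms = 3000)
  expect_equal(sample_trial_type(cfg, prev_blank), "BLANK")

  n <- 20000
  draws <- replicate(n, sample_trial_type(cfg))
  counts <- table(factor(draws, levels = c("CUE", "NOCUE", "BLANK")))
  chi <- suppressWarnings(
    chisq.test(counts, p = c(cfg$p_cue, cfg$p_nocue, cfg$p_blank)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("perturbation delays are truncated-exponential", {
  cfg <- task_config()
  set.seed(7)
  d <- sample_perturbation_delay(cfg, n = 10000)
  expect_true(all(d >= cfg$pert_delay_lo_s))
  expect_true(all(d <= cfg$pert_delay_hi_s))

  m_oracle <- oracle_trunc_exp_mean(1, 2.5, 6)
  expect_equal(m_oracle, 3.391, tolerance = 1e-3)  # closed-form check
  expect_lt(abs(mean(d) - m_oracle), 3 * sd(d) / sqrt(length(d)))

  expect_equal(sample_perturbation_delay(
    task_config(pert_delay_lo_s = 3, pert_delay_hi_s = 3)), 3)
  bad <- task_config()
  bad$pert_delay_lo_s <- 7  # bypass constructor to hit the sampler check
  expect_error(sample_perturbation_delay(bad), "invalid delay")
})

test_that("trapezoidal profile meets amplitude, peak and ramp closed form", {
  p <- make_perturbation_profile(18, 0.2, 140)
  expect_equal(max(p$velocity_mm_s), 140, tolerance = 1e-9)
  expect_equal(p$displacement_mm[length(p$t_s)], 18, tolerance = 1e-9)
  expect_equal(p$ramp_s, 0.2 - 18 / 140, tolerance = 1e-12)
  expect_equal(p$velocity_mm_s[1], 0)
  expect_equal(p$velocity_mm_s[length(p$t_s)], 0)

  expect_error(make_perturbation_profile(0, 0.2, 140), "positive")
  expect_error(make_perturbation_profile(30, 0.2, 140),
               "peak_vel \\* duration")
  expect_error(make_perturbation_profile(10, 0.2, 140), "duration / 2")
})

test_that("profile displacement conserves amplitude across feasible triples", {
  set.seed(21)
  for (i in 1:50) {
    dur <- runif(1, 0.05, 0.5)
    vp <- runif(1, 20, 200)
    amp <- runif(1, 0.55, 0.95) * vp * dur  # strictly inside both bounds
    p <- make_perturbation_profile(amp, dur, vp)
    expect_equal(p$displacement_mm[length(p$t_s)] / amp, 1,
                 tolerance = 1e-6)
    expect_equal(max(p$velocity_mm_s), vp, tolerance = 1e-6)
    expect_true(all(p$velocity_mm_s >= 0))
    expect_true(all(diff(p$displacement_mm) >= -1e-12))
  }
})

test_that("inter-trial scheduling adds the 20-s abort penalty", {
  cfg <- task_config()
  set.seed(3)
  expect_equal(schedule_intertrial(FALSE,
    task_config(iti_lo_s = 10, iti_hi_s = 10)), 10)
  ok <- replicate(2000, schedule_intertrial(FALSE, cfg))
  ab <- replicate(2000, schedule_intertrial(TRUE, cfg))
  expect_true(all(ok >= 10 & ok <= 15))
  se_diff <- sqrt(var(ok) / length(ok) + var(ab) / length(ab))
  expect_lt(abs((mean(ab) - mean(ok)) - cfg$abort_penalty_s), 3 * se_diff)
})

test_that("state machine transitions implement the trial rules", {
  cfg <- task_config()
  st <- new_task_state(cfg)
  # LED timer then initiating lick: trial starts with an immediate reward
  st <- advance(st, list(kind = "timer", timer = "led", t_ms = 0),
                cfg)$state
  step <- advance(st, list(kind = "lick", t_ms = 500), cfg)
  expect_equal(step$state$phase, "ACTIVE")
  expect_setequal(step$events$kind, c("TRIAL_START", "LICK", "REWARD"))
  expect_true(all(step$events$t_ms == 500))
  # a lick 1 s later is not rewarded (water timer), one at 1.2 s is
  s2 <- advance(step$state, list(kind = "lick", t_ms = 1500), cfg)
  expect_false("REWARD" %in% s2$events$kind)
  s3 <- advance(s2$state, list(kind = "lick", t_ms = 1700), cfg)
  expect_true("REWARD" %in% s3$events$kind)
  # grace expiry aborts exactly 600 ms after the last lick
  s4 <- advance(s3$state, list(kind = "timer", timer = "lick_grace",
                               t_ms = 2300), cfg)
  expect_equal(s4$trial_end$completion, "aborted")
  expect_error(advance(s4$state, list(kind = "timer", timer = "trial_max",
                                      t_ms = 9000), cfg), "undefined")
})

test_that("ideal and absent lickers bound the trial outcomes", {
  cfg <- task_config()
  s <- run_session(cfg, scripted_agent(lick_interval_ms = 150), seed = 5,
                   n_trials = 1)
  expect_equal(s$trials$completion, "complete")
  expect_equal(s$trials$n_rewards, 7)  # 1 + floor(7500 / 1100)
  expect_equal(s$trials$end_ms - s$trials$start_ms, 7500)

  none <- run_session(cfg, scripted_agent(lick_interval_ms = NA), seed = 5,
                      n_trials = 3)
  expect_equal(nrow(none$trials), 0)
  expect_equal(sum(none$events$kind == "REWARD"), 0)
  expect_equal(sum(none$events$kind == "LED_ON"), 1)  # LED stays on
  expect_equal(sum(none$events$kind == "LED_OFF"), 0)
})

test_that("scripted aborts end trials 600 ms after the last lick", {
  cfg <- task_config()
  s <- run_session(cfg, scripted_agent(abort_every = 1, abort_at_ms = 3000),
                   seed = 9, n_trials = 4)
  expect_true(all(s$trials$completion == "aborted"))
  for (i in s$trials$trial_index) {
    licks <- s$events$t_ms[s$events$kind == "LICK" &
                             !is.na(s$events$trial_index) &
                             s$events$trial_index == i]
    expect_equal(s$trials$end_ms[i], max(licks) + cfg$lick_grace_ms)
  }
})

test_that("session invariants hold for a stochastic agent", {
  cfg <- task_config()
  s <- run_session(cfg, mouse_agent(), seed = 101, n_trials = 60,
                   session_index = 2)
  ev <- s$events
  expect_true(all(diff(ev$t_ms) >= 0))

  for (i in s$trials$trial_index) {
    tev <- ev[!is.na(ev$trial_index) & ev$trial_index == i, ]
    rewards <- tev$t_ms[tev$kind == "REWARD"]
    expect_lte(length(rewards), 7)
    if (length(rewards) > 1)
      expect_true(all(diff(rewards) >= cfg$water_timer_ms))
    # rewards only inside the trial
    expect_true(all(rewards >= s$trials$start_ms[i] &
                      rewards <= s$trials$end_ms[i]))
    if (s$trials$completion[i] == "aborted") {
      licks <- tev$t_ms[tev$kind == "LICK"]
      expect_equal(s$trials$end_ms[i] - max(licks), cfg$lick_grace_ms)
    } else {
      expect_equal(s$trials$end_ms[i] - s$trials$start_ms[i],
                   1000 * cfg$trial_max_s)
    }
  }
  # no rewards or trial starts during the inter-trial interval
  expect_true(all(!is.na(ev$trial_index[ev$kind %in%
                                          c("REWARD", "TRIAL_START")])))
  # cue geometry on delivered CUE trials
  cue <- s$trials[s$trials$trial_type == "CUE" &
                    !is.na(s$trials$pert_onset_ms) &
                    !is.na(s$trials$cue_on_ms), ]
  expect_gt(nrow(cue), 5)
  expect_true(all(cue$pert_onset_ms - cue$cue_on_ms ==
                    1000 * cfg$cue_lead_s))
  expect_true(all(cue$cue_off_ms == cue$pert_offset_ms))
})

test_that("always-aborting-pre-stimulus agents repeat the trial type", {
  # licking stops 200 ms in, so every abort (at 800 ms) precedes the cue
  # (>= 1.5 s after the first lick) and the perturbation (>= 2.5 s)
  s <- run_session(task_config(), scripted_agent(abort_every = 1,
                                                 abort_at_ms = 200),
                   seed = 13, n_trials = 30)
  expect_true(all(s$trials$completion == "aborted"))
  expect_equal(length(unique(s$trials$trial_type)), 1)
})

test_that("identical seeds give byte-identical event logs", {
  cfg <- task_config()
  f1 <- tempfile(); f2 <- tempfile()
  write_event_log(run_session(cfg, mouse_agent(), seed = 77,
                              n_trials = 20, poses = TRUE)$events, f1)
  write_event_log(run_session(cfg, mouse_agent(), seed = 77,
                              n_trials = 20, poses = TRUE)$events, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  f3 <- tempfile()
  write_event_log(run_session(cfg, mouse_agent(), seed = 78,
                              n_trials = 20, poses = TRUE)$events, f3)
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})
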