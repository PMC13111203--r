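# Virtual mouse: lick renewal process, pause law, synthetic pose tracks
# and dataset generation.

test_that("inter-lick intervals follow the gamma renewal closed forms", {
  ag <- mouse_agent()
  set.seed(31)
  licks <- agent_trial_licks(ag, 0, horizon_ms = 1.6e6)
  gaps <- diff(licks)
  n <- length(gaps)
  expect_gt(n, 9000)
  expect_lt(abs(mean(gaps) - 150), 3 * sd(gaps) / sqrt(n))
  # gamma SD = mean / sqrt(shape); allow for 1-ms rounding
  expect_equal(sd(gaps), 150 / sqrt(10), tolerance = 0.05)
})

test_that("initiation latency drifts only when engagement decays", {
  set.seed(32)
  ag0 <- mouse_agent(engagement_decay = 0)
  l1 <- replicate(300, agent_init_latency(ag0, 1))
  l80 <- replicate(300, agent_init_latency(ag0, 80))
  expect_lt(abs(mean(l1) - mean(l80)),
            3 * sqrt(var(l1) / 300 + var(l80) / 300))
  ag <- mouse_agent(engagement_decay = 15)
  m80 <- mean(replicate(300, agent_init_latency(ag, 80)))
  expect_gt(m80, mean(l1) + 500)  # 79 trials x 15 ms ~ +1185 ms
})

test_that("pause law matches its lognormal closed forms", {
  ag <- mouse_agent()
  set.seed(33)
  p <- sample_pause(rep("NOCUE", 20000), 1, 1, ag)
  med <- median(p)
  # median of LN(mu, sigma) is exp(mu); 99% CI on the sample median
  expect_equal(log(med), ag$pause_mu_log, tolerance = 0.03)
  expect_equal(sd(log(p)), ag$pause_sigma_log, tolerance = 0.03)
  expect_identical(sample_pause("BLANK", 1, 1, ag), 0)

  # null case: no cue/session effects => identical CUE and NOCUE laws
  ag0 <- mouse_agent(cue_effect = 0, session_effect = 0, trial_effect = 0)
  a <- sample_pause(rep("CUE", 3000), 1, 1, ag0)
  b <- sample_pause(rep("NOCUE", 3000), 1, 1, ag0)
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 1e-3)
})

test_that("cue-effect calibration hits a target odds ratio", {
  ag <- mouse_agent(session_effect = 0, trial_effect = 0)
  ag$cue_effect <- calibrate_cue_effect(2.0, ag, grace_ms = 600)
  set.seed(34)
  pc <- sample_pause(rep("CUE", 2e5), 1, 1, ag)
  pn <- sample_pause(rep("NOCUE", 2e5), 1, 1, ag)
  or_hat <- (mean(pc < 600) / (1 - mean(pc < 600))) /
            (mean(pn < 600) / (1 - mean(pn < 600)))
  expect_equal(or_hat, 2.0, tolerance = 0.05)
})

test_that("synthetic traces rise after 50-100 ms and peak at movement end", {
  ag <- mouse_agent(noise_sd_mm = 0, low_lik_frac = 0,
                    response_amp_sd_mm = 0)
  trial <- data.frame(trial_index = 1, session_index = 1,
                      trial_type = "NOCUE", start_ms = 1000, end_ms = 8500,
                      pert_onset_ms = 4000, pert_offset_ms = 4200,
                      cue_on_ms = NA)
  set.seed(35)
  for (r in 1:20) {
    pt <- generate_pose_track(trial, ag)
    tr <- compute_nose_distance(pt)
    pre <- tr$distance_px[tr$t_ms < 4000]
    # flat before onset up to sub-mm coordinate jitter
    expect_lt(diff(range(pre)) * 0.18, 1.5)
    peak_t <- tr$t_ms[which.max(tr$distance_px)]
    expect_gte(peak_t, 4000 + 150)
    expect_lte(peak_t, 4000 + 250)
    # recovery is shallower than the rise
    rise_ms <- peak_t - (4000 + attr(pt, "response_delay_ms"))
    dec <- tr$distance_px[tr$t_ms >= peak_t]
    half <- which(dec - min(pre) <= max(dec - min(pre)) / 2)[1] * 5
    expect_gt(half, rise_ms / 2)
  }
})

test_that("BLANK trials stay at baseline within noise", {
  ag <- mouse_agent(low_lik_frac = 0)
  trial <- data.frame(trial_index = 2, session_index = 1,
                      trial_type = "BLANK", start_ms = 1000, end_ms = 8500,
                      pert_onset_ms = NA, pert_offset_ms = NA,
                      cue_on_ms = NA)
  set.seed(36)
  pt <- generate_pose_track(trial, ag)
  d_mm <- compute_nose_distance(pt)$distance_px * 0.18
  expect_lt(max(abs(d_mm - mean(d_mm))), 5 * ag$noise_sd_mm)
})

test_that("kinematics round-trip recovers generated response amplitudes", {
  ag <- mouse_agent(low_lik_frac = 0)
  trial <- data.frame(trial_index = 1, session_index = 1,
                      trial_type = "NOCUE", start_ms = 1000, end_ms = 8500,
                      pert_onset_ms = 4000, pert_offset_ms = 4200,
                      cue_on_ms = NA)
  set.seed(37)
  diffs <- replicate(60, {
    pt <- generate_pose_track(trial, ag)
    tr <- cap_trace(compute_nose_distance(pt))
    max_nose_distance(tr, 4000) - attr(pt, "response_amp_mm")
  })
  # per-trial recovery error is dominated by frame noise, far below the
  # between-trial amplitude SD
  expect_lt(mean(abs(diffs)), ag$response_amp_sd_mm / 2)
  expect_lt(abs(mean(diffs)), 3 * ag$noise_sd_mm)
})

test_that("stronger cues weakly improve success and weakly damp responses", {
  base <- mouse_agent(session_effect = 0, trial_effect = 0)
  effs <- c(0, 0.3, 0.8)
  succ <- amp <- numeric(length(effs))
  for (k in seq_along(effs)) {
    ag <- base
    ag$cue_effect <- effs[k]
    ag$amp_cue_mm <- 10 * effs[k]
    set.seed(38)  # common random numbers across effect levels
    tab <- simulate_trial_table(ag, n_sessions = 4,
                                trials_per_session = 200,
                                lin_session_re_sd = 0)
    succ[k] <- mean(tab$success[tab$cue == 1])
    amp[k] <- mean(tab$max_nose_mm[tab$cue == 1])
  }
  expect_true(all(diff(succ) >= 0))
  expect_true(all(diff(amp) <= 0))
})

test_that("session effects produce non-increasing session means", {
  ag <- mouse_agent(response_amp_sd_mm = 0, amp_trial_mm = 0)
  set.seed(39)
  tab <- simulate_trial_table(ag, n_sessions = 8, trials_per_session = 50,
                              lin_session_re_sd = 0)
  m <- tapply(tab$max_nose_mm, tab$session_index, mean)
  expect_true(all(diff(m) <= 1e-9))
})

test_that("truth-table success matches the outcome classifier everywhere", {
  ds <- simulate_dataset(task_config(), mouse_agent(), n_sessions = 2,
                         trials_per_session = 40, seed = 41, poses = FALSE)
  out <- classify_outcomes(ds)
  truth <- ds$truth[ds$truth$delivered %in% TRUE, ]
  key_o <- paste(out$session_index, out$trial_index)
  key_t <- paste(truth$session_index, truth$trial_index)
  expect_setequal(key_o, key_t)
  expect_identical(out$success[order(key_o)],
                   truth$success_truth[order(key_t)])
})

test_that("dataset generation is deterministic and hits the trial mix", {
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(task_config(), mouse_agent(), n_sessions = 2,
                   trials_per_session = 30, seed = 42, out_dir = d1)
  simulate_dataset(task_config(), mouse_agent(), n_sessions = 2,
                   trials_per_session = 30, seed = 42, out_dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  ds <- simulate_dataset(task_config(), mouse_agent(), n_sessions = 6,
                         trials_per_session = 83, seed = 43, poses = FALSE)
  counts <- table(factor(ds$trials$trial_type,
                         levels = c("CUE", "NOCUE", "BLANK")))
  chi <- suppressWarnings(chisq.test(counts, p = c(0.74, 0.13, 0.13)))
  expect_gt(chi$p.value, 1e-4)
})
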