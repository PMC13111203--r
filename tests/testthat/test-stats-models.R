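# Mixed-effects models: table assembly, linear and logistic fits,
# reporting, and parameter recovery.

make_tables <- function(seed = 71, n_sessions = 3, trials = 40) {
  ds <- simulate_dataset(task_config(), mouse_agent(), seed = seed,
                         n_sessions = n_sessions,
                         trials_per_session = trials, poses = TRUE)
  list(summaries = summarize_kinematics(ds),
       outcomes = classify_outcomes(ds))
}

test_that("trial-table assembly joins, filters and restricts sessions", {
  tt <- make_tables()
  tab <- build_trial_table(tt$summaries, tt$outcomes)
  expect_setequal(unique(tab$cue), c(0, 1))
  expect_equal(nrow(tab), nrow(tt$outcomes))  # one row per pert trial
  expect_true(all(is.na(tab$max_nose_mm[tab$excluded])))

  r <- build_trial_table(tt$summaries, tt$outcomes, session_range = c(2, 3))
  expect_setequal(unique(r$session_index), 2:3)

  expect_warning(
    empty <- build_trial_table(tt$summaries[0, ], tt$outcomes[0, ]),
    "empty")
  expect_equal(nrow(empty), 0)

  orphan <- tt$summaries
  orphan$trial_index[1] <- 9999
  expect_error(build_trial_table(orphan, tt$outcomes), "join error")
})

test_that("linear mixed model recovers the generative amplitude law", {
  ag <- mouse_agent()
  set.seed(72)
  tab <- simulate_trial_table(ag, n_sessions = 11, trials_per_session = 80)
  fit <- fit_lmm(tab)
  truth <- implied_linear_truth(ag)
  co <- fit$coefficients
  expect_equal(co$term, c("(Intercept)", "cue", "trial", "session"))
  for (term in c("cue", "trial", "session")) {
    row <- co[co$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 4 * row$se)
  }
  expect_lt(co$p[co$term == "cue"], 0.05)
  expect_equal(fit$n_obs, sum(!tab$excluded))
})

test_that("fixed effects approach OLS when the session variance vanishes", {
  ag <- mouse_agent(amp_session_mm = 0)
  set.seed(73)
  tab <- simulate_trial_table(ag, n_sessions = 6, trials_per_session = 60,
                              lin_session_re_sd = 0)
  fit <- suppressWarnings(fit_lmm(tab))
  ols <- lm(max_nose_mm ~ cue + trial + session_index, data = tab)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 0.02)
})

test_that("observation-level random intercept falls back with a warning", {
  tt <- make_tables(seed = 74)
  tab <- build_trial_table(tt$summaries, tt$outcomes)
  expect_warning(fit <- fit_lmm(tab, include_trial_re = TRUE),
                 "not identifiable")
  expect_s3_class(fit, "perch_fit")
})

test_that("logistic model reports coherent exponentiated coefficients", {
  ag <- mouse_agent(session_effect = 0, trial_effect = 0)
  ag$cue_effect <- calibrate_cue_effect(2.5, ag)
  set.seed(75)
  tab <- simulate_trial_table(ag, n_sessions = 8, trials_per_session = 100)
  fit <- fit_logistic_mm(tab)
  co <- fit$coefficients
  expect_equal(co$exp_estimate, exp(co$estimate), tolerance = 1e-12)
  expect_true(all(co$exp_lo > 0 & co$exp_lo <= co$exp_estimate &
                    co$exp_estimate <= co$exp_hi))
  cue <- co[co$term == "cue", ]
  expect_lt(abs(cue$estimate - log(2.5)), 4 * cue$se)
})

test_that("degenerate outcome tables are rejected informatively", {
  tab <- data.frame(animal_id = "x",
                    session_index = rep(1:2, each = 20),
                    trial = rep(1:20, 2),
                    cue = rep(c(0, 1), 20),
                    max_nose_mm = rnorm(40, 50),
                    success = rep(c(0, 1), 20),  # success == cue
                    excluded = FALSE)
  suppressWarnings(expect_error(fit_logistic_mm(tab), "separation"))
  one_session <- tab[tab$session_index == 1, ]
  expect_error(fit_lmm(one_session), "2 sessions")
  no_nocue <- tab
  no_nocue$cue <- 1
  expect_error(fit_lmm(no_nocue), "CUE and NOCUE")
  const <- tab
  const$success <- 1
  expect_error(fit_logistic_mm(const), "constant")
})

test_that("fit results are invariant to row order", {
  ag <- mouse_agent()
  set.seed(76)
  tab <- simulate_trial_table(ag, n_sessions = 4, trials_per_session = 50)
  f1 <- fit_lmm(tab)
  set.seed(77)
  f2 <- fit_lmm(tab[sample(nrow(tab)), ])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("reports mirror the published table layouts and round-trip", {
  tt <- make_tables(seed = 78)
  tab <- build_trial_table(tt$summaries, tt$outcomes)
  lin <- fit_lmm(tab)
  txt <- report(lin)
  expect_length(txt, 2 + 4)  # header rows + b0, b_cue, b_trial, b_session
  expect_match(txt[2], "Standard error")
  log_fit <- fit_logistic_mm(tab)
  expect_match(report(log_fit)[2], "Exp")
  f <- tempfile(fileext = ".csv")
  report(log_fit, "csv", f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$estimate, log_fit$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(back$term, log_fit$coefficients$term)
})

test_that("recovery experiments are deterministic and score coverage", {
  ag <- mouse_agent(session_effect = 0, trial_effect = 0)
  ag$cue_effect <- calibrate_cue_effect(2.0, ag)
  r1 <- recovery_experiment(ag, n_replicates = 5, seed = 79,
                            n_sessions = 5, trials_per_session = 40)
  r2 <- recovery_experiment(ag, n_replicates = 5, seed = 79,
                            n_sessions = 5, trials_per_session = 40)
  expect_identical(r1$summary, r2$summary)
  expect_setequal(r1$summary$term,
                  c("(Intercept)", "cue", "trial", "session"))
  expect_true(all(r1$summary$coverage >= 0 & r1$summary$coverage <= 1))
  expect_equal(unique(r1$estimates$replicate), 1:5)
})

test_that("the deposited-data reader validates its schema", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "CB5", session_index = 1, trial = 1,
                       cue = 1, max_nose_mm = 50, success = 1), f,
            row.names = FALSE)
  d <- load_dryad_trials(f)
  expect_true("excluded" %in% names(d))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(load_dryad_trials(bad), "lacks column")
  expect_error(load_dryad_trials(tempfile()), "not found")
})
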