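## Trial-outcome classification from event logs and session summaries.

#' Classify the outcome of one perturbation trial
#'
#' A trial is a success if the mouse obtained at least one water droplet
#' after the perturbation: by default strictly after the end of the
#' platform movement (`after = "offset"`); `after = "onset"` switches to
#' the looser reading (any reward after the perturbation began).
#'
#' @param trial one trial record row (CUE or NOCUE with a delivered
#'   perturbation).
#' @param events event log data frame (`t_ms`, `kind`, `trial_index`).
#' @param after reference point: `"offset"` (default) or `"onset"`.
#' @return a one-row data frame: `trial_index`, `session_index`,
#'   `trial_type`, `success`, `droplets`, `first_post_pert_reward_ms`.
#' @export
classify_outcome <- function(trial, events, after = c("offset", "onset")) {
  after <- match.arg(after)
  type <- as.character(trial$trial_type)
  if (!type %in% c("CUE", "NOCUE"))
    stop("outcome is defined only for perturbation (CUE/NOCUE) trials",
         call. = FALSE)
  ev <- events[!is.na(events$trial_index) &
                 events$trial_index == trial$trial_index, ]
  pert_on <- ev$t_ms[ev$kind == "PERT_ON"]
  pert_off <- ev$t_ms[ev$kind == "PERT_OFF"]
  if (length(pert_on) != 1 || length(pert_off) != 1)
    stop("log integrity: perturbation trial ", trial$trial_index,
         " lacks PERT_ON/PERT_OFF events", call. = FALSE)
  ref <- if (after == "offset") pert_off else pert_on
  rewards <- ev$t_ms[ev$kind == "REWARD"]
  post <- rewards[rewards > ref]
  data.frame(trial_index = trial$trial_index,
             session_index = trial$session_index,
             trial_type = type,
             success = length(post) > 0,
             droplets = length(rewards),
             first_post_pert_reward_ms =
               if (length(post)) min(post) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Classify all perturbation trials of a session or dataset
#'
#' Applies [classify_outcome()] to every CUE/NOCUE trial whose perturbation
#' was delivered. BLANK trials and trials aborted before their scheduled
#' perturbation are not part of the outcome analysis.
#'
#' @param x a `perch_session` or `perch_dataset`, or a list with `trials`
#'   and `events`.
#' @param after see [classify_outcome()].
#' @return data frame of per-trial outcomes.
#' @export
classify_outcomes <- function(x, after = c("offset", "onset")) {
  after <- match.arg(after)
  if (inherits(x, "perch_dataset"))
    return(do.call(rbind, lapply(x$sessions, classify_outcomes,
                                 after = after)))
  trials <- x$trials
  keep <- trials$trial_type %in% c("CUE", "NOCUE") &
    !is.na(trials$pert_onset_ms)
  rows <- lapply(which(keep), function(j)
    classify_outcome(trials[j, ], x$events, after = after))
  if (!length(rows))
    return(data.frame(trial_index = integer(0), session_index = integer(0),
                      trial_type = character(0), success = logical(0),
                      droplets = integer(0),
                      first_post_pert_reward_ms = numeric(0)))
  cbind(do.call(rbind, rows), animal_id = trials$animal_id[keep][1])
}

#' Droplet-count distribution
#'
#' Histogram of the number of water droplets received per trial (0-7),
#' optionally split by trial outcome. Successful trials concentrate at the
#' 7-droplet maximum; failed trials spread over lower counts according to
#' when the perturbation fell.
#'
#' @param outcomes data frame from [classify_outcomes()].
#' @param by_success split the histogram by outcome.
#' @param max_droplets largest count in the support.
#' @return data frame with `droplets`, `count` (and `success` when split).
#' @export
droplet_distribution <- function(outcomes, by_success = FALSE,
                                 max_droplets = 7) {
  lev <- 0:max_droplets
  if (!by_success) {
    counts <- tabulate(factor(outcomes$droplets, levels = lev),
                       nbins = length(lev))
    return(data.frame(droplets = lev, count = counts))
  }
  do.call(rbind, lapply(c(FALSE, TRUE), function(s) {
    d <- outcomes$droplets[outcomes$success == s]
    data.frame(success = s, droplets = lev,
               count = tabulate(factor(d, levels = lev),
                                nbins = length(lev)))
  }))
}

#' Binomial confidence interval for a success proportion
#'
#' Clopper-Pearson exact interval by default (beta quantiles); Wilson score
#' interval available by flag.
#'
#' @param n_success,n_trials counts.
#' @param level confidence level.
#' @param method `"clopper"` or `"wilson"`.
#' @return list with `proportion`, `lo`, `hi`.
#' @export
success_ci <- function(n_success, n_trials, level = 0.95,
                       method = c("clopper", "wilson")) {
  method <- match.arg(method)
  if (n_trials < 1 || n_success < 0 || n_success > n_trials)
    stop("need 0 <= n_success <= n_trials and n_trials >= 1", call. = FALSE)
  p <- n_success / n_trials
  a <- (1 - level) / 2
  if (method == "clopper") {
    lo <- if (n_success == 0) 0 else
      stats::qbeta(a, n_success, n_trials - n_success + 1)
    hi <- if (n_success == n_trials) 1 else
      stats::qbeta(1 - a, n_success + 1, n_trials - n_success)
  } else {
    z <- stats::qnorm(1 - a)
    den <- 1 + z^2 / n_trials
    cen <- (p + z^2 / (2 * n_trials)) / den
    hw <- z * sqrt(p * (1 - p) / n_trials + z^2 / (4 * n_trials^2)) / den
    lo <- max(0, cen - hw)
    hi <- min(1, cen + hw)
  }
  list(proportion = p, lo = lo, hi = hi)
}

#' Sliding-window success proportion
#'
#' Centered moving proportion of successful trials over trial order, with
#' the window shrinking at the session edges. For even window widths the
#' extra trial is taken on the trailing side.
#'
#' @param success logical/0-1 vector in trial order.
#' @param window window width in trials.
#' @return numeric vector of the same length.
#' @export
sliding_success <- function(success, window = 10) {
  stopifnot(window >= 1)
  x <- as.numeric(success)
  n <- length(x)
  if (!n) return(numeric(0))
  lead <- floor(window / 2)
  lag <- floor((window - 1) / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - lead)
    hi <- min(n, i + lag)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Per-session outcome summaries
#'
#' Success counts and proportions with binomial 95% confidence intervals
#' for each session.
#'
#' @param outcomes data frame from [classify_outcomes()].
#' @param level confidence level.
#' @param method interval method, see [success_ci()].
#' @return data frame with one row per session.
#' @export
summarize_sessions <- function(outcomes, level = 0.95,
                               method = c("clopper", "wilson")) {
  method <- match.arg(method)
  do.call(rbind, lapply(split(outcomes, outcomes$session_index),
    function(d) {
      ci <- success_ci(sum(d$success), nrow(d), level, method)
      data.frame(session_index = d$session_index[1], n_trials = nrow(d),
                 n_success = sum(d$success), proportion = ci$proportion,
                 ci_lo = ci$lo, ci_hi = ci$hi)
    }))
}
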