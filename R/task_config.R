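#' Task configuration
#'
#' Every timing, probability and geometry parameter of the postural task.
#' Defaults are the published values of the paradigm: a 600-ms lick-grace
#' window, a 1,100-ms water (reward-refractory) timer, 7.5-s maximum trial
#' duration, 10-15-s uniform inter-trial interval with a 20-s abort penalty
#' and a 5-s no-lick gate, a cue leading the perturbation by 1 s, a
#' perturbation delay drawn from an exponential of mean 1 s truncated to
#' 2.5-6 s, and a 200-ms backward platform translation.
#'
#' @param lick_grace_ms maximum lick-free interval before the trial aborts.
#' @param water_timer_ms refractory period after a reward before the next
#'   lick can be rewarded.
#' @param trial_max_s maximum trial duration (complete trials last exactly
#'   this long).
#' @param iti_lo_s,iti_hi_s bounds of the uniform inter-trial interval.
#' @param abort_penalty_s extra interval added after aborted trials.
#' @param nolick_gate_s required lick-free period before the LED can turn on.
#' @param cue_lead_s interval from cue onset to perturbation onset.
#' @param pert_delay_mean_s underlying exponential mean of the perturbation
#'   delay (measured from the trial's first lick).
#' @param pert_delay_lo_s,pert_delay_hi_s truncation bounds of the delay.
#' @param pert_duration_s platform translation duration.
#' @param pert_amplitude_mm platform displacement amplitude; the study used
#'   7 (small), 12 (medium) or 18 (large) mm.
#' @param pert_peak_vel_mm_s peak platform velocity; 60, 100 or 140 mm/s
#'   paired with the three amplitudes.
#' @param return_vel_mm_s slow return speed during the inter-trial interval.
#' @param p_cue,p_nocue,p_blank trial-type probabilities (must sum to 1).
#' @param reward_ul water droplet volume, microlitres.
#' @param max_trials default number of trials per session (study median 83).
#' @param dt_s simulation tick, seconds.
#' @return an object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config()
#' cfg$lick_grace_ms
#' @export
task_config <- function(lick_grace_ms = 600,
                        water_timer_ms = 1100,
                        trial_max_s = 7.5,
                        iti_lo_s = 10,
                        iti_hi_s = 15,
                        abort_penalty_s = 20,
                        nolick_gate_s = 5,
                        cue_lead_s = 1.0,
                        pert_delay_mean_s = 1.0,
                        pert_delay_lo_s = 2.5,
                        pert_delay_hi_s = 6.0,
                        pert_duration_s = 0.2,
                        pert_amplitude_mm = 18,
                        pert_peak_vel_mm_s = 140,
                        return_vel_mm_s = 57,
                        p_cue = 0.74,
                        p_nocue = 0.13,
                        p_blank = 0.13,
                        reward_ul = 2,
                        max_trials = 83L,
                        dt_s = 0.001) {
  cfg <- list(
    lick_grace_ms = lick_grace_ms, water_timer_ms = water_timer_ms,
    trial_max_s = trial_max_s, iti_lo_s = iti_lo_s, iti_hi_s = iti_hi_s,
    abort_penalty_s = abort_penalty_s, nolick_gate_s = nolick_gate_s,
    cue_lead_s = cue_lead_s, pert_delay_mean_s = pert_delay_mean_s,
    pert_delay_lo_s = pert_delay_lo_s, pert_delay_hi_s = pert_delay_hi_s,
    pert_duration_s = pert_duration_s, pert_amplitude_mm = pert_amplitude_mm,
    pert_peak_vel_mm_s = pert_peak_vel_mm_s, return_vel_mm_s = return_vel_mm_s,
    p_cue = p_cue, p_nocue = p_nocue, p_blank = p_blank,
    reward_ul = reward_ul, max_trials = as.integer(max_trials), dt_s = dt_s)
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  durs <- c("lick_grace_ms", "water_timer_ms", "trial_max_s", "iti_lo_s",
            "iti_hi_s", "abort_penalty_s", "nolick_gate_s", "cue_lead_s",
            "pert_delay_mean_s", "pert_duration_s", "dt_s")
  for (d in durs) {
    v <- cfg[[d]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("task_config: '", d, "' must be a single positive number",
           call. = FALSE)
  }
  ps <- c(cfg$p_cue, cfg$p_nocue, cfg$p_blank)
  if (any(ps < 0) || any(ps > 1))
    stop("task_config: trial-type probabilities must lie in [0, 1]",
         call. = FALSE)
  if (abs(sum(ps) - 1) > 1e-9)
    stop("task_config: p_cue + p_nocue + p_blank must equal 1 (got ",
         format(sum(ps), digits = 12), ")", call. = FALSE)
  if (cfg$pert_delay_lo_s > cfg$pert_delay_hi_s)
    stop("task_config: pert_delay_lo_s must not exceed pert_delay_hi_s",
         call. = FALSE)
  if (cfg$pert_delay_lo_s < cfg$cue_lead_s)
    stop("task_config: pert_delay_lo_s must be >= cue_lead_s, otherwise the ",
         "cue could be scheduled before the trial starts", call. = FALSE)
  if (cfg$iti_lo_s > cfg$iti_hi_s)
    stop("task_config: iti_lo_s must not exceed iti_hi_s", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  for (n in names(x)) cat(sprintf("  %-20s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Standard perturbation parameter sets
#'
#' The three amplitude/peak-velocity pairs used in the study: small
#' (7 mm, 60 mm/s), medium (12 mm, 100 mm/s) and large (18 mm, 140 mm/s),
#' all with a 200-ms duration.
#'
#' @param size one of `"small"`, `"medium"`, `"large"`.
#' @return a list with `pert_amplitude_mm`, `pert_peak_vel_mm_s`,
#'   `pert_duration_s`.
#' @export
perturbation_preset <- function(size = c("large", "medium", "small")) {
  size <- match.arg(size)
  amp <- c(small = 7, medium = 12, large = 18)[[size]]
  vel <- c(small = 60, medium = 100, large = 140)[[size]]
  list(pert_amplitude_mm = amp, pert_peak_vel_mm_s = vel,
       pert_duration_s = 0.2)
}
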