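#' Trapezoidal platform velocity profile
#'
#' Builds the platform displacement profile for one perturbation. Only the
#' amplitude, duration and peak velocity of the translation are constrained
#' by the paradigm; the waveform used here is a symmetric trapezoid, the
#' unique symmetric piecewise-linear profile satisfying all three. The ramp
#' time on each side is `t_r = duration - amplitude / peak_vel`, so the
#' plateau lasts `2 * amplitude / peak_vel - duration`.
#'
#' Feasibility requires `peak_vel * duration / 2 < amplitude <
#' peak_vel * duration` (strictly): below the lower bound the platform
#' cannot reach the peak velocity and return to rest in time; above the
#' upper bound the displacement cannot be achieved at that peak velocity.
#'
#' Velocity is the backward speed magnitude (non-negative); direction is
#' carried in the `direction` attribute. The displacement series is the
#' exact closed-form integral of the trapezoid evaluated on the grid, and
#' the grid contains the two ramp kink times in addition to the regular
#' `dt` ticks so the peak is always represented exactly.
#'
#' @param amplitude_mm total displacement, mm (7, 12 or 18 in the study).
#' @param duration_s movement duration, s (0.2 in the study).
#' @param peak_vel_mm_s peak velocity, mm/s (60, 100 or 140 in the study).
#' @param dt_s time step of the output grid, s.
#' @param direction `"backward"` (task default) or `"forward"`.
#' @return an object of class `perturbation_profile`: a list with `t_s`,
#'   `velocity_mm_s`, `displacement_mm`, `ramp_s` and the input parameters.
#' @examples
#' p <- make_perturbation_profile(18, 0.2, 140)
#' max(p$velocity_mm_s)               # 140
#' p$displacement_mm[length(p$t_s)]   # 18
#' @export
make_perturbation_profile <- function(amplitude_mm, duration_s = 0.2,
                                      peak_vel_mm_s, dt_s = 0.001,
                                      direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  if (!is.numeric(amplitude_mm) || length(amplitude_mm) != 1 ||
      !is.finite(amplitude_mm) || amplitude_mm <= 0)
    stop("amplitude_mm must be a single positive number", call. = FALSE)
  if (duration_s <= 0 || peak_vel_mm_s <= 0 || dt_s <= 0)
    stop("duration_s, peak_vel_mm_s and dt_s must be positive", call. = FALSE)
  if (amplitude_mm >= peak_vel_mm_s * duration_s)
    stop(sprintf(paste0(
      "infeasible profile: amplitude (%.6g mm) must be < peak_vel * ",
      "duration = %.6g mm"), amplitude_mm, peak_vel_mm_s * duration_s),
      call. = FALSE)
  if (amplitude_mm <= peak_vel_mm_s * duration_s / 2)
    stop(sprintf(paste0(
      "infeasible profile: amplitude (%.6g mm) must be > peak_vel * ",
      "duration / 2 = %.6g mm"), amplitude_mm,
      peak_vel_mm_s * duration_s / 2), call. = FALSE)

  t_r <- duration_s - amplitude_mm / peak_vel_mm_s
  t <- seq(0, duration_s, by = dt_s)
  if (t[length(t)] < duration_s) t <- c(t, duration_s)
  t <- sort(unique(c(t, t_r, duration_s - t_r)))

  v <- pmax(0, peak_vel_mm_s *
              pmin(t / t_r, 1, (duration_s - t) / t_r))
  # exact running integral of the trapezoid
  d <- ifelse(t <= t_r,
              peak_vel_mm_s * t^2 / (2 * t_r),
       ifelse(t <= duration_s - t_r,
              peak_vel_mm_s * (t - t_r / 2),
              amplitude_mm - peak_vel_mm_s * (duration_s - t)^2 / (2 * t_r)))
  d[length(d)] <- amplitude_mm

  structure(list(t_s = t, velocity_mm_s = v, displacement_mm = d,
                 ramp_s = t_r, amplitude_mm = amplitude_mm,
                 duration_s = duration_s, peak_vel_mm_s = peak_vel_mm_s,
                 direction = direction),
            class = "perturbation_profile")
}

#' @export
print.perturbation_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<perturbation_profile> %s trapezoid: %.3g mm in %.3g s, peak %.4g ",
    "mm/s, ramps %.4g s\n"), x$direction, x$amplitude_mm, x$duration_s,
    x$peak_vel_mm_s, x$ramp_s))
  invisible(x)
}
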