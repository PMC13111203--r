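## Nose-distance kinematics: tracking-quality handling -> Euclidean
## distance -> 450-px cap -> baseline subtraction -> onset exclusion ->
## windowed summary. The pipeline order is fixed; each stage is exported.

#' Pixel-to-millimetre calibration
#'
#' A single isotropic scale, 0.18 mm/px by default (450 px = 81 mm in the
#' recorded view). No lens or projective correction is applied: the
#' analysis is single-camera 2D.
#'
#' @param mm_per_px millimetres per pixel.
#' @export
calibration_scale <- function(mm_per_px = 0.18) {
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1, mm_per_px > 0)
  structure(list(mm_per_px = mm_per_px), class = "calibration_scale")
}

#' Convert pixels to millimetres
#'
#' @param px pixel value(s).
#' @param scale a [calibration_scale()].
#' @return millimetres; e.g. 450 px -> 81 mm, 225 px -> 40.5 mm at the
#'   default scale.
#' @export
px_to_mm <- function(px, scale = calibration_scale()) {
  stopifnot(inherits(scale, "calibration_scale"))
  px * scale$mm_per_px
}

#' Interpolate low-likelihood tracking frames
#'
#' Frames whose nose likelihood falls below `threshold` are linearly
#' interpolated from the surrounding good frames when the bad run is at
#' most `max_gap_frames` long; longer runs are left untouched and flag the
#' trial for exclusion or manual review (the study handled such trials by
#' manual annotation). Counts are attached as attributes
#' `low_likelihood_frames` and `tracking_flagged`.
#'
#' @param pose a `pose_track` data frame.
#' @param threshold likelihood threshold.
#' @param max_gap_frames longest run of bad frames that is interpolated.
#' @return the pose track with interpolated coordinates and flag
#'   attributes.
#' @export
flag_low_likelihood <- function(pose, threshold = 0.9, max_gap_frames = 10) {
  if (!("nose_likelihood" %in% names(pose)))
    stop("pose track has no likelihood channel", call. = FALSE)
  bad <- pose$nose_likelihood < threshold
  attr(pose, "low_likelihood_frames") <- sum(bad)
  attr(pose, "tracking_flagged") <- FALSE
  if (!any(bad)) return(pose)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flagged <- FALSE
  fix <- logical(nrow(pose))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (r$lengths[k] <= max_gap_frames) fix[starts[k]:ends[k]] <- TRUE
    else flagged <- TRUE
  }
  if (any(fix)) {
    good <- !bad
    if (sum(good) >= 2) {
      for (col in c("nose_x", "nose_y")) {
        pose[[col]][fix] <- stats::approx(pose$frame[good],
                                          pose[[col]][good],
                                          xout = pose$frame[fix],
                                          rule = 2)$y
      }
    } else flagged <- TRUE
  }
  attr(pose, "tracking_flagged") <- flagged
  pose
}

#' Per-frame nose-to-spout distance
#'
#' Euclidean distance between the tracked nose and spout points in each
#' video frame, in pixels.
#'
#' @param pose a `pose_track` data frame with `nose_x`, `nose_y`,
#'   `spout_x`, `spout_y` (and `t_ms`).
#' @return a `nose_trace` data frame: `frame`, `t_ms`, `distance_px`.
#' @export
compute_nose_distance <- function(pose) {
  need <- c("nose_x", "nose_y", "spout_x", "spout_y")
  miss <- setdiff(need, names(pose))
  if (length(miss))
    stop("pose track is missing bodypart column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(frame = pose$frame, t_ms = pose$t_ms,
                    distance_px = sqrt((pose$nose_x - pose$spout_x)^2 +
                                       (pose$nose_y - pose$spout_y)^2))
  class(out) <- c("nose_trace", "data.frame")
  out
}

#' Cap a nose-distance trace
#'
#' Distances beyond `cap_px` (450 px = 81 mm) are capped; at that distance
#' the mouse has come down from bipedal standing and larger values reflect
#' off-target motion.
#'
#' @param trace a `nose_trace`.
#' @param cap_px cap, pixels.
#' @return the trace with capped `distance_px` and a logical `capped`
#'   column.
#' @export
cap_trace <- function(trace, cap_px = 450) {
  trace$capped <- trace$distance_px > cap_px
  trace$distance_px <- pmin(trace$distance_px, cap_px)
  trace
}

#' Baseline nose distance before the perturbation
#'
#' Mean of the (capped) nose distance over the window 250-2,250 ms before
#' the perturbation onset, closed at both ends on the 5-ms frame grid.
#'
#' @param trace a `nose_trace` (cap first: the pipeline order is cap, then
#'   baseline).
#' @param pert_onset_ms perturbation onset, ms.
#' @param window_ms length-2 vector: start and end of the window, ms
#'   before the onset.
#' @return baseline, pixels.
#' @export
compute_baseline <- function(trace, pert_onset_ms,
                             window_ms = c(2250, 250)) {
  w <- sort(window_ms, decreasing = TRUE)
  sel <- trace$t_ms >= pert_onset_ms - w[1] &
         trace$t_ms <= pert_onset_ms - w[2]
  if (!any(sel))
    stop("baseline unavailable: no frames in [onset-", w[1], ", onset-",
         w[2], "] ms", call. = FALSE)
  mean(trace$distance_px[sel])
}

# index of the analysis onset frame: nearest frame at or after the onset,
# falling back to the nearest frame overall
onset_frame_index <- function(trace, pert_onset_ms) {
  at_or_after <- which(trace$t_ms >= pert_onset_ms)
  if (length(at_or_after)) at_or_after[1]
  else which.min(abs(trace$t_ms - pert_onset_ms))
}

#' Exclude a trial by its posture at perturbation onset
#'
#' Trials where the raw capped nose distance at the onset frame exceeds
#' 225 px (= 40.5 mm, strictly) are excluded: the mouse was ducking down
#' rather than standing upright, so its perturbation response is not
#' comparable.
#'
#' @param trace a capped `nose_trace`.
#' @param pert_onset_ms perturbation onset, ms.
#' @param threshold_px exclusion threshold, pixels.
#' @return logical: `TRUE` if the trial is excluded.
#' @export
exclude_by_onset <- function(trace, pert_onset_ms, threshold_px = 225) {
  i <- onset_frame_index(trace, pert_onset_ms)
  trace$distance_px[i] > threshold_px
}

#' Maximum nose distance after the perturbation
#'
#' The per-trial kinematic performance measure: the maximum of the
#' baseline-subtracted, capped nose distance over the window from the
#' perturbation onset to 250 ms after it (closed on the frame grid),
#' converted to mm. Alternative summaries over the same window (`mean`,
#' `median`, area under the trace) are available via `stat`; `raw = TRUE`
#' skips the baseline subtraction.
#'
#' @param trace a capped `nose_trace`.
#' @param pert_onset_ms perturbation onset, ms.
#' @param window_ms window length after onset, ms.
#' @param scale a [calibration_scale()].
#' @param baseline baseline in px (from [compute_baseline()]); computed
#'   from the trace if `NULL`.
#' @param stat summary statistic over the window.
#' @param raw use the raw capped trace instead of the baseline-subtracted
#'   one.
#' @return summary value in mm (for `stat = "auc"`, mm x s).
#' @export
max_nose_distance <- function(trace, pert_onset_ms, window_ms = 250,
                              scale = calibration_scale(), baseline = NULL,
                              stat = c("max", "mean", "median", "auc"),
                              raw = FALSE) {
  stat <- match.arg(stat)
  sel <- trace$t_ms >= pert_onset_ms &
         trace$t_ms <= pert_onset_ms + window_ms
  if (!any(sel))
    stop("no video frames in the [onset, onset+", window_ms, "] ms window",
         call. = FALSE)
  x <- trace$distance_px[sel]
  if (!raw) {
    if (is.null(baseline))
      baseline <- compute_baseline(trace, pert_onset_ms)
    x <- x - baseline
  }
  v <- switch(stat,
              max = max(x),
              mean = mean(x),
              median = stats::median(x),
              auc = sum((x[-1] + x[-length(x)]) / 2 *
                          diff(trace$t_ms[sel]) / 1000))
  px_to_mm(v, scale)
}

#' Per-trial kinematic summaries for a session or dataset
#'
#' Applies the full pipeline (likelihood handling, distance, cap, baseline,
#' onset exclusion, windowed maximum) to every delivered perturbation trial
#' (CUE/NOCUE with the platform actually moved) of a simulated session or
#' dataset. Trials without a pose track are flagged `excluded_no_video`
#' (their event data remain usable for outcome analysis); trials failing
#' the onset-posture rule are flagged `excluded_onset`; both carry `NA`
#' maxima.
#'
#' @param x a `perch_session` or `perch_dataset` (with poses), or a list of
#'   pose tracks with a matching `trials` data frame.
#' @param ... passed to the stage functions: `cap_px`, `onset_threshold_px`,
#'   `baseline_window_ms`, `window_ms`, `scale`, `lik_threshold`,
#'   `max_gap_frames`, `raw`.
#' @return a data frame with one row per analyzed trial: identifiers,
#'   `max_nose_mm`, exclusion flags and the low-likelihood frame count.
#' @export
summarize_kinematics <- function(x, ...) UseMethod("summarize_kinematics")

#' @export
summarize_kinematics.perch_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$sessions, summarize_kinematics, ...))
}

#' @export
summarize_kinematics.perch_session <- function(x, ...) {
  kinematics_table(x$trials, x$poses, ...)
}

#' @rdname summarize_kinematics
#' @param trials trial-record data frame (as in `perch_session$trials`).
#' @param poses list of pose tracks indexed like the trials.
#' @param scale a [calibration_scale()].
#' @param cap_px,onset_threshold_px,baseline_window_ms,window_ms pipeline
#'   parameters (see the stage functions).
#' @param lik_threshold,max_gap_frames tracking-quality parameters.
#' @param raw report the raw-trace maximum instead of the
#'   baseline-subtracted one.
#' @export
kinematics_table <- function(trials, poses, scale = calibration_scale(),
                             cap_px = 450, onset_threshold_px = 225,
                             baseline_window_ms = c(2250, 250),
                             window_ms = 250, lik_threshold = 0.9,
                             max_gap_frames = 10, raw = FALSE) {
  keep <- trials$trial_type %in% c("CUE", "NOCUE") &
    !is.na(trials$pert_onset_ms)
  idx <- which(keep)
  rows <- lapply(idx, function(j) {
    tr <- trials[j, ]
    pose <- if (j <= length(poses)) poses[[j]] else NULL
    out <- data.frame(
      animal_id = tr$animal_id, session_index = tr$session_index,
      trial_index = tr$trial_index, trial_type = tr$trial_type,
      max_nose_mm = NA_real_, excluded_onset = FALSE,
      excluded_no_video = FALSE, tracking_flagged = FALSE,
      low_likelihood_frames = NA_integer_, stringsAsFactors = FALSE)
    if (is.null(pose)) {
      out$excluded_no_video <- TRUE
      return(out)
    }
    pose <- flag_low_likelihood(pose, lik_threshold, max_gap_frames)
    out$low_likelihood_frames <- attr(pose, "low_likelihood_frames")
    out$tracking_flagged <- attr(pose, "tracking_flagged")
    trace <- cap_trace(compute_nose_distance(pose), cap_px)
    out$excluded_onset <- exclude_by_onset(trace, tr$pert_onset_ms,
                                           onset_threshold_px)
    if (!out$excluded_onset) {
      out$max_nose_mm <- max_nose_distance(
        trace, tr$pert_onset_ms, window_ms = window_ms, scale = scale,
        baseline = compute_baseline(trace, tr$pert_onset_ms,
                                    baseline_window_ms),
        raw = raw)
    }
    out
  })
  do.call(rbind, rows)
}
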