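## On-disk formats: newline-delimited event logs (append-only, diffable,
## the software analogue of a TTL record), flat CSV exports, the 3-header
## pose-estimation CSV dialect, YAML task configuration, and the pipeline
## run manifest.

#' Write an event log
#'
#' Newline-delimited records with fields `t_ms` (integer, session-relative
#' milliseconds), `kind` (event type) and `trial_index` (integer, `null`
#' for inter-trial events). Formatting is fixed, so identical simulations
#' produce byte-identical files.
#'
#' @param events event data frame (`t_ms`, `kind`, `trial_index`).
#' @param path output file (conventionally `events.ndjson`).
#' @export
write_event_log <- function(events, path) {
  ti <- ifelse(is.na(events$trial_index), "null",
               as.character(as.integer(events$trial_index)))
  lines <- sprintf('{"t_ms":%d,"kind":"%s","trial_index":%s}',
                   as.integer(round(events$t_ms)), events$kind, ti)
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate an event log
#'
#' Parses a newline-delimited event log and validates it: timestamps must
#' be non-decreasing and every `kind` known. Violations are reported with
#' the first offending line number.
#'
#' @param path event log file.
#' @return validated event data frame.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  lines <- readLines(path)
  ev <- tryCatch(
    jsonlite::stream_in(textConnection(lines), verbose = FALSE),
    error = function(e) stop("event log parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("t_ms", "kind", "trial_index")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event log missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_kind <- which(!ev$kind %in% EVENT_KINDS)
  if (length(bad_kind))
    stop("event log parse error at line ", bad_kind[1], ": unknown kind '",
         ev$kind[bad_kind[1]], "'", call. = FALSE)
  drop <- which(diff(ev$t_ms) < 0)
  if (length(drop))
    stop("event log parse error at line ", drop[1] + 1,
         ": timestamps are not non-decreasing", call. = FALSE)
  ev$trial_index <- as.integer(ev$trial_index)
  ev[, need]
}

#' @rdname write_event_log
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("t_ms", "kind", "trial_index")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a pose track in the pose-estimation CSV dialect
#'
#' Three header rows (scorer, bodyparts, coords) and x/y/likelihood
#' columns per bodypart, matching single-animal tracking output so that
#' real tracking files are drop-in replacements for synthetic ones.
#'
#' @param pose a `pose_track` data frame, or a list of them (concatenated
#'   in order; frames are renumbered consecutively).
#' @param path output CSV path.
#' @param scorer scorer string for the first header row.
#' @export
write_pose_csv <- function(pose, path, scorer = "perchtask") {
  if (!is.data.frame(pose)) {
    pose <- do.call(rbind, lapply(pose, function(p)
      p[, c("nose_x", "nose_y", "nose_likelihood",
            "spout_x", "spout_y", "spout_likelihood")]))
  }
  header <- c(paste(c("scorer", rep(scorer, 6)), collapse = ","),
              paste(c("bodyparts", rep(c("nose", "spout"), each = 3)),
                    collapse = ","),
              paste(c("coords", rep(c("x", "y", "likelihood"), 2)),
                    collapse = ","))
  vals <- cbind(pose$nose_x, pose$nose_y, pose$nose_likelihood,
                pose$spout_x, pose$spout_y, pose$spout_likelihood)
  body <- sprintf("%d,%s", seq_len(nrow(vals)) - 1L,
                  apply(vals, 1, function(r)
                    paste(sprintf("%.10g", r), collapse = ",")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a pose-estimation CSV
#'
#' Parses the 3-header-row dialect. Bodyparts other than nose and spout
#' are preserved in the returned frame but ignored downstream; a missing
#' likelihood column is an error.
#'
#' @param path CSV path.
#' @return a `pose_track` data frame (`frame`, then
#'   `<bodypart>_<coord>` columns). Frame times are not part of the
#'   dialect; attach them from FRAME events with [split_pose_by_trial()].
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose CSV not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3 || !startsWith(hdr[2], "bodyparts") ||
      !startsWith(hdr[3], "coords"))
    stop("malformed pose CSV header: expected scorer/bodyparts/coords ",
         "rows in ", path, call. = FALSE)
  parts <- strsplit(hdr[2], ",")[[1]][-1]
  coords <- strsplit(hdr[3], ",")[[1]][-1]
  if (length(parts) != length(coords))
    stop("malformed pose CSV header: bodyparts/coords length mismatch",
         call. = FALSE)
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  if (ncol(dat) != length(parts) + 1)
    stop("pose CSV has ", ncol(dat) - 1, " data columns but the header ",
         "declares ", length(parts), call. = FALSE)
  cn <- paste(parts, coords, sep = "_")
  names(dat) <- c("frame", cn)
  for (bp in unique(parts)) {
    if (!paste0(bp, "_likelihood") %in% cn)
      stop("pose CSV bodypart '", bp, "' has no likelihood column",
           call. = FALSE)
  }
  class(dat) <- c("pose_track", "data.frame")
  dat
}

#' Split a session pose file into per-trial tracks with frame times
#'
#' FRAME events in the event log are the single source of truth mapping
#' frame index to session time: the i-th data row of the session's pose
#' CSV corresponds to the i-th FRAME event. This attaches `t_ms` and
#' splits the rows by the FRAME events' trial index.
#'
#' @param pose pose track from [read_pose_csv()] (whole session).
#' @param events validated event log containing FRAME events.
#' @return named list of per-trial `pose_track`s (names = trial index).
#' @export
split_pose_by_trial <- function(pose, events) {
  fr <- events[events$kind == "FRAME", ]
  if (nrow(fr) != nrow(pose))
    stop("frame-sync mismatch: ", nrow(fr), " FRAME events but ",
         nrow(pose), " pose rows", call. = FALSE)
  pose$t_ms <- fr$t_ms
  out <- split(pose, fr$trial_index)
  lapply(out, function(p) {
    p$frame <- seq_len(nrow(p)) - 1L
    class(p) <- c("pose_track", "data.frame")
    p
  })
}

#' Read/write a task configuration file
#'
#' Flat YAML mirroring the [task_config()] field names; values read from
#' file are validated by the constructor.
#'
#' @param config a [task_config()].
#' @param path file path.
#' @export
write_task_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(task_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(task_config, vals)
}

#' Write a simulated dataset to disk
#'
#' One event log (`events_sNN.ndjson`) and, when poses were generated, one
#' pose CSV (`poses_sNN.csv`) per session, plus combined `trials.csv` and
#' `truth.csv` tables and the `config.yaml` used.
#'
#' @param ds a `perch_dataset`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  for (s in ds$sessions) {
    tag <- sprintf("s%02d", s$session_index)
    write_event_log(s$events, file.path(out_dir,
                                        paste0("events_", tag, ".ndjson")))
    if (!is.null(s$poses))
      write_pose_csv(s$poses, file.path(out_dir,
                                        paste0("poses_", tag, ".csv")))
  }
  utils::write.csv(ds$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  write_task_config(ds$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a dataset directory back into session objects
#'
#' Inverse of [write_dataset()] for the analysis-only path: reloads the
#' per-session event logs, pose CSVs (split back into per-trial tracks via
#' FRAME events) and the combined trial table.
#'
#' @param dir dataset directory.
#' @return a `perch_dataset` (without agent truth unless `truth.csv`
#'   exists).
#' @export
read_dataset <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  config <- read_task_config(file.path(dir, "config.yaml"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  sessions <- lapply(sort(unique(trials$session_index)), function(si) {
    tag <- sprintf("s%02d", si)
    events <- read_event_log(file.path(dir,
                                       paste0("events_", tag, ".ndjson")))
    tr <- trials[trials$session_index == si, ]
    pose_path <- file.path(dir, paste0("poses_", tag, ".csv"))
    poses <- NULL
    if (file.exists(pose_path)) {
      by_trial <- split_pose_by_trial(read_pose_csv(pose_path), events)
      poses <- vector("list", nrow(tr))
      poses[as.integer(names(by_trial))] <- by_trial
    }
    structure(list(session_index = si, animal_id = tr$animal_id[1],
                   config = config, trials = tr, events = events,
                   poses = poses, truth = NULL),
              class = "perch_session")
  })
  structure(list(sessions = sessions, trials = trials, truth = truth,
                 config = config, animal_id = trials$animal_id[1]),
            class = "perch_dataset")
}

md5_of <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline
#'
#' Simulate (or reuse) a dataset, run the kinematic and outcome analyses,
#' fit the mixed models, and write every product plus a run manifest to
#' `out_dir`. The manifest records the package version, master seed,
#' configuration hash and an MD5 per output file; identical seeds and
#' configurations yield identical output hashes.
#'
#' @param config a [task_config()].
#' @param agent a `perch_agent`.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param n_sessions,trials_per_session design size.
#' @param session_range optional session restriction for the model fits.
#' @param dataset optionally, an existing `perch_dataset` (skips
#'   simulation).
#' @param fit_models fit the mixed models (needs >= 2 sessions and both
#'   cue levels).
#' @return the manifest, invisibly.
#' @export
pipeline <- function(config = task_config(), agent = mouse_agent(),
                     seed = 1L, out_dir, n_sessions = 11,
                     trials_per_session = config$max_trials,
                     session_range = NULL, dataset = NULL,
                     fit_models = TRUE) {
  stage <- "simulate"
  manifest <- list(tool = "perchtask",
                   version = as.character(utils::packageVersion("perchtask")),
                   seed = seed, stages = character(0))
  result <- tryCatch({
    ds <- if (is.null(dataset))
      simulate_dataset(config, agent, n_sessions, trials_per_session,
                       seed = seed, out_dir = out_dir, poses = TRUE)
    else { write_dataset(dataset, out_dir); dataset }
    manifest$stages <- c(manifest$stages, "simulate")

    stage <- "kinematics"
    summaries <- summarize_kinematics(ds)
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)
    manifest$stages <- c(manifest$stages, "kinematics")

    stage <- "outcomes"
    outcomes <- classify_outcomes(ds)
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(summarize_sessions(outcomes),
                     file.path(out_dir, "sessions.csv"), row.names = FALSE)
    manifest$stages <- c(manifest$stages, "outcomes")

    stage <- "fit"
    tab <- build_trial_table(summaries, outcomes, session_range)
    utils::write.csv(tab, file.path(out_dir, "trial_table.csv"),
                     row.names = FALSE)
    if (fit_models) {
      report(fit_lmm(tab), "csv", file.path(out_dir, "fit_linear.csv"))
      report(fit_logistic_mm(tab), "csv",
             file.path(out_dir, "fit_logistic.csv"))
    }
    manifest$stages <- c(manifest$stages, "fit")
    TRUE
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_tmp <- tempfile(fileext = ".yaml")
  write_task_config(config, cfg_tmp)
  manifest$config_md5 <- md5_of(cfg_tmp)
  unlink(cfg_tmp)
  outs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest$outputs <- stats::setNames(
    lapply(outs, function(f) md5_of(file.path(out_dir, f))), outs)
  manifest$finished_at <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
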