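#' Finger-trajectory log schema
#'
#' A trajectory log holds one row per 60 Hz touch sample:
#' `subject_id`, `group` (1 or 2), `phase` (1 or 2), `session` (1-6),
#' `trial_id`, `exercise_type`, `t_ms` (ms from trial onset), `x_pct`/`y_pct`
#' (percent of screen width/height) and `touching` (logical; `FALSE` rows are
#' retained but break fixation/saccade streaks).
#'
#' @name trajectory-schema
#' @keywords internal
NULL

.traj_cols <- c("subject_id", "group", "phase", "session", "trial_id",
                "exercise_type", "t_ms", "x_pct", "y_pct", "touching")

#' Validate a trajectory table
#'
#' Checks the column set, coordinate ranges, per-trial strictly increasing
#' timestamps, and (optionally) the nominal sampling interval against the
#' geometry's rate with a relative tolerance (tablet schedulers jitter).
#'
#' @param traj A data.frame following the trajectory schema.
#' @param geometry Optional [screen_geometry()]; when supplied the
#'   inter-sample interval is checked against `1000 / sampling_rate` ms.
#' @param interval_tolerance Allowed relative deviation of each inter-sample
#'   interval from nominal (default 0.25).
#' @return `traj` invisibly, with class `digitrace_trajectories`; errors name
#'   the offending rows.
#' @export
validate_trajectories <- function(traj, geometry = NULL,
                                  interval_tolerance = 0.25) {
  missing_cols <- setdiff(.traj_cols, names(traj))
  if (length(missing_cols)) {
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_xy <- which(traj$x_pct < 0 | traj$x_pct > 100 |
                  traj$y_pct < 0 | traj$y_pct > 100 | traj$t_ms < 0)
  if (length(bad_xy)) {
    stop("coordinates or timestamps out of range at rows: ",
         paste(utils::head(bad_xy, 10), collapse = ", "), call. = FALSE)
  }
  key <- interaction(traj$subject_id, traj$phase, traj$session, traj$trial_id,
                     drop = TRUE)
  ord <- order(key, traj$t_ms)
  dup_or_back <- integer()
  for (idx in split(seq_len(nrow(traj))[ord], key[ord])) {
    dt <- diff(traj$t_ms[idx])
    bad <- which(dt <= 0)
    if (length(bad)) dup_or_back <- c(dup_or_back, idx[bad + 1L])
    if (!is.null(geometry)) {
      nominal <- 1000 / geometry$sampling_rate
      off <- which(abs(dt - nominal) > interval_tolerance * nominal)
      if (length(off)) {
        warning(sprintf(
          "trial %s/%s/%s: %d inter-sample interval(s) deviate >%g%% from %.1f ms",
          traj$subject_id[idx[1]], traj$session[idx[1]], traj$trial_id[idx[1]],
          length(off), 100 * interval_tolerance, nominal), call. = FALSE)
      }
    }
  }
  if (length(dup_or_back)) {
    stop("non-increasing timestamps within a trial at rows: ",
         paste(utils::head(sort(dup_or_back), 10), collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(traj, "digitrace_trajectories")) {
    class(traj) <- c("digitrace_trajectories", class(traj))
  }
  invisible(traj)
}

#' Read finger-trajectory logs
#'
#' Reads the CSV (or JSON-lines) trajectory dialect, validates it, and returns
#' one table ordered by subject, phase, session, trial and time.
#'
#' @param path Path to a `.csv` or `.jsonl` file.
#' @param format File format; inferred from the extension by default.
#' @param geometry Optional [screen_geometry()] passed to
#'   [validate_trajectories()].
#' @return A validated `digitrace_trajectories` data.frame.
#' @export
read_trajectories <- function(path, format = c("auto", "csv", "jsonl"),
                              geometry = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  traj <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(readLines(path), function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  }
  traj$touching <- as.logical(traj$touching)
  traj <- traj[order(traj$subject_id, traj$phase, traj$session, traj$trial_id,
                     traj$t_ms), , drop = FALSE]
  rownames(traj) <- NULL
  validate_trajectories(traj, geometry = geometry)
  class(traj) <- c("digitrace_trajectories", "data.frame")
  traj
}

#' Write finger-trajectory logs to CSV
#'
#' @param traj A trajectory table (see [validate_trajectories()]).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_trajectories <- function(traj, path) {
  missing_cols <- setdiff(.traj_cols, names(traj))
  if (length(missing_cols)) {
    stop("trajectory table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(as.data.frame(traj)[, .traj_cols], path, row.names = FALSE)
  invisible(path)
}

# Split a trajectory table into per-trial data.frames (ordered by time).
.split_trials <- function(traj) {
  key <- interaction(traj$subject_id, traj$phase, traj$session, traj$trial_id,
                     drop = TRUE, sep = "\r")
  lapply(split(seq_len(nrow(traj)), key),
         function(idx) traj[idx[order(traj$t_ms[idx])], , drop = FALSE])
}
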