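#' Per-sample finger speeds for one trial
#'
#' Computes the Euclidean displacement between consecutive touch samples,
#' converts it to millimetres via the geometry's pixel pitch, and divides by
#' the inter-sample interval. The speed is attributed to the later sample of
#' each pair; the first sample of a trial carries no speed (`NA`). Pairs that
#' span a finger-lift (either sample has `touching = FALSE`) produce no speed
#' value.
#'
#' @param trial One trial of trajectory samples ordered by `t_ms` (columns
#'   `t_ms`, `x_pct`, `y_pct`, `touching`).
#' @param geometry A [screen_geometry()].
#' @return `trial` with added columns `x_px`, `y_px` and `speed_mm_s`.
#' @examples
#' g <- screen_geometry()
#' tr <- data.frame(t_ms = c(0, 1000/60), x_pct = c(0, 3/19.2),
#'                  y_pct = c(0, 4/12.8), touching = TRUE)
#' compute_speeds(tr, g)$speed_mm_s  # NA, 40.5
#' @export
compute_speeds <- function(trial, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  n <- nrow(trial)
  px <- percent_to_pixels(trial$x_pct, trial$y_pct, geometry)
  trial$x_px <- px$x_px
  trial$y_px <- px$y_px
  if (n < 2L) {
    if (n > 0L) warning("fewer than 2 samples; no speeds computed", call. = FALSE)
    trial$speed_mm_s <- rep(NA_real_, n)
    return(trial)
  }
  d_px <- sqrt(diff(px$x_px)^2 + diff(px$y_px)^2)
  dt_s <- diff(trial$t_ms) / 1000
  sp <- d_px * geometry$pixel_pitch / dt_s
  gap <- !(trial$touching[-1] & trial$touching[-n])
  sp[gap] <- NA_real_
  trial$speed_mm_s <- c(NA_real_, sp)
  trial
}

#' Median-speed threshold for one subject-session
#'
#' The individual segmentation threshold is the median of all strictly
#' positive speeds pooled across every trial of a subject-session (null
#' values — zero speeds and missing frames — are excluded first). The median
#' was adopted because, across a large range of candidate thresholds, it
#' detects the most fixations; see [threshold_sweep()] for the diagnostic.
#'
#' @param speeds Numeric vector of speeds (mm/s) pooled over the
#'   subject-session's trials, or a data.frame with a `speed_mm_s` column.
#' @return The threshold (mm/s).
#' @examples
#' median_speed_threshold(c(0, 0, 1, 2, 3, 4, 5)) # 3
#' @export
median_speed_threshold <- function(speeds) {
  if (is.data.frame(speeds)) speeds <- speeds$speed_mm_s
  pos <- speeds[!is.na(speeds) & speeds > 0]
  if (length(pos) == 0L) {
    stop("degenerate trace: no strictly positive speeds", call. = FALSE)
  }
  stats::median(pos)
}

# Classify each sample as "slow", "fast" or "gap".
# - sample i >= 2: by speed_mm_s[i] vs threshold; ties go to "slow"
#   (at-threshold = not moving fast). Ties are resolved with a relative
#   tolerance so that speeds equal to the threshold up to floating-point
#   rounding (exact ties are common in regular-grid recordings, where the
#   median is itself one of the observed speeds) classify as at-threshold.
# - untouched samples are "gap".
# - touched samples with NA speed (trial start, first touch after a lift)
#   join the class of the next classified sample (or previous, at the end).
.classify_samples <- function(speed, touching, threshold,
                              tie_tolerance = 1e-8) {
  n <- length(speed)
  cls <- rep(NA_character_, n)
  cls[!touching] <- "gap"
  known <- touching & !is.na(speed)
  cls[known] <- ifelse(speed[known] <= threshold * (1 + tie_tolerance),
                       "slow", "fast")
  # resolve pending samples from the right, then remaining from the left
  nxt <- NA_character_
  for (i in n:1) {
    if (!is.na(cls[i])) nxt <- if (cls[i] == "gap") NA_character_ else cls[i]
    else if (!is.na(nxt)) cls[i] <- nxt
  }
  prev <- NA_character_
  for (i in seq_len(n)) {
    if (!is.na(cls[i])) prev <- if (cls[i] == "gap") NA_character_ else cls[i]
    else if (!is.na(prev)) cls[i] <- prev
  }
  cls[is.na(cls)] <- "slow"  # isolated touched samples with no neighbours
  cls
}

# Greedy left-to-right split of one slow run into fixations whose member
# samples stay within the dispersion box (range < limits, strict).
.split_fixation_run <- function(x, y, limits) {
  n <- length(x)
  starts <- integer(); ends <- integer()
  s <- 1L
  mnx <- x[1]; mxx <- x[1]; mny <- y[1]; mxy <- y[1]
  for (i in seq_len(n)[-1]) {
    nmnx <- min(mnx, x[i]); nmxx <- max(mxx, x[i])
    nmny <- min(mny, y[i]); nmxy <- max(mxy, y[i])
    if ((nmxx - nmnx) >= limits[1] || (nmxy - nmny) >= limits[2]) {
      starts <- c(starts, s); ends <- c(ends, i - 1L)
      s <- i
      mnx <- x[i]; mxx <- x[i]; mny <- y[i]; mxy <- y[i]
    } else {
      mnx <- nmnx; mxx <- nmxx; mny <- nmny; mxy <- nmxy
    }
  }
  starts <- c(starts, s); ends <- c(ends, n)
  cbind(starts, ends)
}

#' Segment one trial into digital fixations and saccades
#'
#' Implements the median-speed rule: maximal streaks of contiguous samples
#' moving slower than (or exactly at) the threshold become digital fixations;
#' maximal faster streaks become digital saccades. Finger-lift samples break
#' streaks. Slow streaks whose spatial spread reaches the dispersion limits
#' (5.8 px in X, 6.4 px in Y — about 0.3%/0.5% of the study screen) are split
#' greedily left-to-right at the first violating sample.
#'
#' Per event the function reports:
#' * fixations: start/end time, duration (`end_t - start_t` over member
#'   samples), barycenter (coordinate-wise mean of member positions), sample
#'   count;
#' * saccades: mean speed over member samples, length in mm (distance between
#'   the barycenters of the flanking fixations; `NA` if a flank is missing),
#'   and direction — progressive if the X of the saccade's last sample exceeds
#'   the X of its first sample, regressive otherwise (ties are regressive).
#'
#' @param trial One trial of samples (see [compute_speeds()]; the speed column
#'   is computed here if absent).
#' @param threshold Median-speed threshold (mm/s) from the same
#'   subject-session, as produced by [median_speed_threshold()].
#' @param geometry A [screen_geometry()].
#' @param dispersion_px Length-2 numeric, maximal X/Y spread of a fixation in
#'   px.
#' @param min_fixation_ms Optional duration floor; fixations shorter than this
#'   are dropped (default 0: no floor).
#' @return A list with data.frames `fixations` (`event`, `start_t`, `end_t`,
#'   `duration_ms`, `barycenter_x`, `barycenter_y`, `n_samples`, `start_idx`,
#'   `end_idx`) and `saccades` (`event`, `start_t`, `end_t`, `n_samples`,
#'   `length_mm`, `mean_speed_mm_s`, `direction`, `from_fixation`,
#'   `to_fixation`, `start_idx`, `end_idx`).
#' @export
segment_trajectory <- function(trial, threshold, geometry,
                               dispersion_px = c(5.8, 6.4),
                               min_fixation_ms = 0) {
  stopifnot(length(dispersion_px) == 2L, all(dispersion_px > 0),
            threshold > 0)
  if (is.null(trial$speed_mm_s)) trial <- compute_speeds(trial, geometry)
  n <- nrow(trial)
  empty_fix <- data.frame(event = integer(), start_t = numeric(),
                          end_t = numeric(), duration_ms = numeric(),
                          barycenter_x = numeric(), barycenter_y = numeric(),
                          n_samples = integer(), start_idx = integer(),
                          end_idx = integer())
  empty_sac <- data.frame(event = integer(), start_t = numeric(),
                          end_t = numeric(), n_samples = integer(),
                          length_mm = numeric(), mean_speed_mm_s = numeric(),
                          direction = character(), from_fixation = integer(),
                          to_fixation = integer(), start_idx = integer(),
                          end_idx = integer())
  if (n == 0L) return(list(fixations = empty_fix, saccades = empty_sac))

  cls <- .classify_samples(trial$speed_mm_s, trial$touching, threshold)
  runs <- rle(cls)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  events <- list()  # each: list(type, idx_start, idx_end)
  for (r in seq_along(runs$values)) {
    if (runs$values[r] == "gap") next
    i0 <- run_start[r]; i1 <- run_end[r]
    if (runs$values[r] == "fast") {
      events[[length(events) + 1L]] <- list(type = "saccade", s = i0, e = i1)
    } else {
      pieces <- .split_fixation_run(trial$x_px[i0:i1], trial$y_px[i0:i1],
                                    dispersion_px)
      for (p in seq_len(nrow(pieces))) {
        events[[length(events) + 1L]] <-
          list(type = "fixation", s = i0 + pieces[p, 1] - 1L,
               e = i0 + pieces[p, 2] - 1L)
      }
    }
  }
  if (length(events) == 0L) return(list(fixations = empty_fix, saccades = empty_sac))

  types <- vapply(events, `[[`, "", "type")
  fx <- which(types == "fixation")
  fix_rows <- lapply(seq_along(fx), function(k) {
    ev <- events[[fx[k]]]
    idx <- ev$s:ev$e
    data.frame(event = fx[k], start_t = trial$t_ms[ev$s],
               end_t = trial$t_ms[ev$e],
               duration_ms = trial$t_ms[ev$e] - trial$t_ms[ev$s],
               barycenter_x = mean(trial$x_px[idx]),
               barycenter_y = mean(trial$y_px[idx]),
               n_samples = length(idx), start_idx = ev$s, end_idx = ev$e)
  })
  fixations <- if (length(fix_rows)) do.call(rbind, fix_rows) else empty_fix
  if (min_fixation_ms > 0 && nrow(fixations)) {
    fixations <- fixations[fixations$duration_ms >= min_fixation_ms, ,
                           drop = FALSE]
  }

  sc <- which(types == "saccade")
  sac_rows <- lapply(seq_along(sc), function(k) {
    ev <- events[[sc[k]]]
    idx <- ev$s:ev$e
    # flanking fixations (nearest fixation event before/after in event order)
    before <- fx[fx < sc[k]]
    after <- fx[fx > sc[k]]
    from_i <- if (length(before)) max(before) else NA_integer_
    to_i <- if (length(after)) min(after) else NA_integer_
    len <- NA_real_
    if (!is.na(from_i) && !is.na(to_i)) {
      b0 <- fixations[fixations$event == from_i, ]
      b1 <- fixations[fixations$event == to_i, ]
      if (nrow(b0) == 1L && nrow(b1) == 1L) {
        len <- sqrt((b1$barycenter_x - b0$barycenter_x)^2 +
                    (b1$barycenter_y - b0$barycenter_y)^2) *
               geometry$pixel_pitch
      }
    }
    spd <- trial$speed_mm_s[idx]
    data.frame(event = sc[k], start_t = trial$t_ms[ev$s],
               end_t = trial$t_ms[ev$e], n_samples = length(idx),
               length_mm = len, mean_speed_mm_s = mean(spd, na.rm = TRUE),
               direction = if (trial$x_px[ev$e] > trial$x_px[ev$s])
                 "progressive" else "regressive",
               from_fixation = from_i, to_fixation = to_i,
               start_idx = ev$s, end_idx = ev$e,
               stringsAsFactors = FALSE)
  })
  saccades <- if (length(sac_rows)) do.call(rbind, sac_rows) else empty_sac
  list(fixations = fixations, saccades = saccades)
}

#' Per-trial kinematic summary
#'
#' Aggregates one trial's segmented events into the study's dependent
#' variables: number and mean duration of digital fixations, number of
#' saccades by direction, proportion of regressive saccades (the ratio of
#' regressive to total saccades; reported as `NA` — not 0 — for saccade-free
#' trials so that aggregates are not biased toward zero), mean saccade length
#' and mean saccade speed.
#'
#' @param fixations,saccades Output of [segment_trajectory()] for one trial.
#' @return A one-row data.frame.
#' @export
trial_kinematics <- function(fixations, saccades) {
  n_sac <- nrow(saccades)
  n_reg <- sum(saccades$direction == "regressive")
  data.frame(
    n_fixations = nrow(fixations),
    mean_fixation_duration_ms = if (nrow(fixations)) mean(fixations$duration_ms) else NA_real_,
    n_saccades = n_sac,
    n_progressive = n_sac - n_reg,
    n_regressive = n_reg,
    proportion_regressive = if (n_sac > 0) n_reg / n_sac else NA_real_,
    mean_saccade_length_mm = if (n_sac && any(!is.na(saccades$length_mm)))
      mean(saccades$length_mm, na.rm = TRUE) else NA_real_,
    mean_saccade_speed_mm_s = if (n_sac) mean(saccades$mean_speed_mm_s) else NA_real_
  )
}

#' Fixation counts across candidate thresholds
#'
#' Diagnostic reproducing the empirical argument for the median threshold:
#' across a range of candidate speed thresholds, count the digital fixations
#' that [segment_trajectory()] detects. The package reports the sweep; it does
#' not assert that the median maximises the count on any given trace.
#'
#' @param trial One trial of samples.
#' @param thresholds Numeric vector of candidate thresholds (mm/s).
#' @param geometry A [screen_geometry()].
#' @param ... Passed to [segment_trajectory()].
#' @return A data.frame with columns `threshold` and `n_fixations`.
#' @export
threshold_sweep <- function(trial, thresholds, geometry, ...) {
  if (length(thresholds) == 0L) stop("no candidate thresholds", call. = FALSE)
  trial <- compute_speeds(trial, geometry)
  data.frame(
    threshold = thresholds,
    n_fixations = vapply(thresholds, function(th)
      nrow(segment_trajectory(trial, th, geometry, ...)$fixations), 0L)
  )
}

#' Segment every trial of a cohort
#'
#' Computes speeds for all trials, pools them per subject-session to obtain
#' each median-speed threshold, segments every trial, and returns tidy event
#' and per-trial kinematics tables carrying the trial identifiers.
#'
#' @param traj A `digitrace_trajectories` table (multiple trials).
#' @param geometry A [screen_geometry()].
#' @param per_trial_threshold Fall back to a per-trial median threshold
#'   (instead of the subject-session pool) — intended for short recordings.
#' @param ... Passed to [segment_trajectory()].
#' @return A list with `thresholds` (subject, phase, session, threshold),
#'   `fixations`, `saccades`, and `kinematics` (one row per trial with
#'   identifiers and [trial_kinematics()] columns).
#' @export
segment_cohort <- function(traj, geometry, per_trial_threshold = FALSE, ...) {
  trials <- .split_trials(traj)
  trials <- lapply(trials, compute_speeds, geometry = geometry)

  ss_key <- vapply(trials, function(tr)
    paste(tr$subject_id[1], tr$phase[1], tr$session[1], sep = "\r"), "")
  thresholds <- new.env(parent = emptyenv())
  for (k in unique(ss_key)) {
    pooled <- unlist(lapply(trials[ss_key == k], `[[`, "speed_mm_s"))
    assign(k, median_speed_threshold(pooled), envir = thresholds)
  }

  fix_list <- list(); sac_list <- list(); kin_list <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    th <- if (per_trial_threshold) median_speed_threshold(tr$speed_mm_s)
          else get(ss_key[i], envir = thresholds)
    seg <- segment_trajectory(tr, th, geometry, ...)
    ids <- tr[1, c("subject_id", "group", "phase", "session", "trial_id",
                   "exercise_type"), drop = FALSE]
    rownames(ids) <- NULL
    if (nrow(seg$fixations)) fix_list[[length(fix_list) + 1L]] <-
      cbind(ids[rep(1, nrow(seg$fixations)), ], seg$fixations)
    if (nrow(seg$saccades)) sac_list[[length(sac_list) + 1L]] <-
      cbind(ids[rep(1, nrow(seg$saccades)), ], seg$saccades)
    kin_list[[length(kin_list) + 1L]] <-
      cbind(ids, threshold = th, trial_kinematics(seg$fixations, seg$saccades))
  }
  th_parts <- do.call(rbind, strsplit(ls(thresholds), "\r"))
  list(
    thresholds = data.frame(subject_id = th_parts[, 1],
                            phase = as.integer(th_parts[, 2]),
                            session = as.integer(th_parts[, 3]),
                            threshold = vapply(ls(thresholds), get, 0,
                                               envir = thresholds),
                            row.names = NULL),
    fixations = if (length(fix_list)) do.call(rbind, fix_list) else NULL,
    saccades = if (length(sac_list)) do.call(rbind, sac_list) else NULL,
    kinematics = do.call(rbind, kin_list)
  )
}
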