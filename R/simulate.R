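# Fixation-jitter constants of the simulator. Nonzero jitter steps have a
# constant magnitude (0.8 px/frame = 6.48 mm/s on the default display) and are
# a majority of all nonzero speeds, so the pooled median-speed threshold of
# every subject-session equals the jitter speed: fixations are never split by
# the threshold and the threshold is identical across decoder groups, which
# keeps the recovered good-poor speed gap unbiased. The walk is folded back
# into a +/-2.4 px box, well inside the 5.8/6.4 px dispersion limits.
.JITTER_STEP_PX <- 0.8
.JITTER_BOX_PX <- 2.4
.JITTER_P_MOVE <- 0.6

#' Reader profile for the trajectory simulator
#'
#' Generative parameters of one decoder group's finger behaviour. Units are
#' the pipeline's native units so parameter recovery is read directly:
#' durations in ms, speeds in mm/s, lengths in mm, landing positions in
#' character units.
#'
#' `session_drift` holds per-session multipliers (length 6, normalised to
#' mean 1 so phase-pooled means equal the profile means) emulating the
#' within-phase training trends: fixation durations shrink, saccades speed up
#' and lengthen from session 1 to 5 and plateau at 6, regressions become
#' rarer over the first four sessions. `phase_offset` holds additive offsets
#' applied in training phase 2 (default 0).
#'
#' @param fixation_duration_ms,fixation_duration_sd_ms Mean and SD of digital
#'   fixation durations.
#' @param saccade_speed_mm_s,saccade_speed_sd_mm_s Mean and SD of the mean
#'   speed of a digital saccade (the simulator's triangular speed ramp peaks
#'   at twice the mean).
#' @param saccade_amplitude_mm Scale of regressive saccade amplitudes.
#' @param p_regressive Probability that any given saccade is regressive.
#' @param landing_mean_short,landing_mean_long Mean first-fixation landing
#'   position (character units) on short (1-6 letters) and long (7-11
#'   letters) words.
#' @param landing_sd_chars SD of the landing position draw.
#' @param refixation_rate Expected refixations per character of a word.
#' @param p_correct Per-item success probability on the decoding assessment.
#' @param session_drift Named list of length-6 multiplier vectors for
#'   `fixation_duration`, `saccade_speed`, `p_regressive`, `amplitude`.
#' @param phase_offset Named list of additive phase-2 offsets for
#'   `fixation_duration`, `saccade_speed`, `p_regressive`.
#' @return A list of class `reader_profile`.
#' @seealso [good_reader_profile()], [poor_reader_profile()]
#' @export
reader_profile <- function(fixation_duration_ms = 400,
                           fixation_duration_sd_ms = 100,
                           saccade_speed_mm_s = 66.8,
                           saccade_speed_sd_mm_s = 8,
                           saccade_amplitude_mm = 6,
                           p_regressive = 0.25,
                           landing_mean_short = 1.60,
                           landing_mean_long = 3.14,
                           landing_sd_chars = 0.3,
                           refixation_rate = 0.06,
                           p_correct = 0.7,
                           session_drift = default_session_drift(),
                           phase_offset = list(fixation_duration = 0,
                                               saccade_speed = 0,
                                               p_regressive = 0)) {
  stopifnot(fixation_duration_ms > 0, saccade_speed_mm_s > 0,
            saccade_amplitude_mm > 0,
            p_regressive >= 0, p_regressive <= 1,
            landing_mean_short >= 0, landing_mean_long >= 0,
            refixation_rate >= 0, p_correct >= 0, p_correct <= 1)
  drift_names <- c("fixation_duration", "saccade_speed", "p_regressive",
                   "amplitude")
  stopifnot(all(drift_names %in% names(session_drift)),
            all(vapply(session_drift[drift_names], length, 0L) == 6L))
  structure(
    list(fixation_duration_ms = fixation_duration_ms,
         fixation_duration_sd_ms = fixation_duration_sd_ms,
         saccade_speed_mm_s = saccade_speed_mm_s,
         saccade_speed_sd_mm_s = saccade_speed_sd_mm_s,
         saccade_amplitude_mm = saccade_amplitude_mm,
         p_regressive = p_regressive,
         landing_mean_short = landing_mean_short,
         landing_mean_long = landing_mean_long,
         landing_sd_chars = landing_sd_chars,
         refixation_rate = refixation_rate,
         p_correct = p_correct,
         session_drift = session_drift,
         phase_offset = phase_offset),
    class = "reader_profile")
}

#' Default within-phase session trends
#'
#' Multipliers per session (1-6), each vector normalised to mean 1: fixation
#' durations shrink over sessions, saccades speed up and lengthen with a
#' plateau at session 6, regressions decline over the first four sessions.
#'
#' @return Named list of length-6 numeric vectors.
#' @export
default_session_drift <- function() {
  list(fixation_duration = c(1.10, 1.06, 1.02, 0.97, 0.93, 0.92),
       saccade_speed     = c(0.94, 0.96, 0.98, 1.03, 1.05, 1.04),
       p_regressive      = c(1.25, 1.12, 1.00, 0.90, 0.87, 0.86),
       amplitude         = c(0.92, 0.94, 0.99, 1.04, 1.06, 1.05))
}

#' Default good-decoder profile
#'
#' Group parameters centred so that the good-poor differences equal the
#' study's printed contrasts: saccade mean speed +13.57 mm/s, fixation
#' duration -68.6 ms (group mean 400 ms), identical regression probability
#' (0.25) and landing means (1.60/3.14; the group contrast there is carried
#' by the word-length effect, not built into the generator). Good decoders
#' refixate half as often and succeed more on the decoding assessment.
#'
#' @return A [reader_profile()].
#' @export
good_reader_profile <- function() {
  reader_profile(fixation_duration_ms = 365.7,
                 saccade_speed_mm_s = 73.57,
                 refixation_rate = 0.04,
                 p_correct = 0.85)
}

#' Default poor-decoder profile
#'
#' @return A [reader_profile()].
#' @seealso [good_reader_profile()]
#' @export
poor_reader_profile <- function() {
  reader_profile(fixation_duration_ms = 434.3,
                 saccade_speed_mm_s = 60.0,
                 refixation_rate = 0.08,
                 p_correct = 0.60)
}

#' Default sentence stimuli for simulated cohorts
#'
#' Four five-word pseudoword sentences mixing short (1-6 letters) and long
#' (7-11 letters) words, laid out on one line each. Geometry only (no
#' raster), which is all the simulator needs.
#'
#' @param geometry A [screen_geometry()].
#' @return A list of `stimulus_image` objects.
#' @export
default_sentence_set <- function(geometry = screen_geometry()) {
  sentences <- c("bora muti faderont lipa vomirade",
                 "nulo pirema sadoventi rafi tolu",
                 "mivo latu boradine supa firelont",
                 "dalo ruvi monterade bilu safenor")
  lapply(sentences, function(s)
    render_text(s, geometry, origin_x = 200,
                origin_y = round(geometry$height_px / 2), raster = FALSE))
}

# Reflect a random-walk coordinate into [-b, b] (triangular fold).
.fold <- function(z, b) {
  p <- (z + b) %% (4 * b)
  ifelse(p <= 2 * b, p - b, 3 * b - p)
}

# Jittered fixation positions: n samples around (cx, cy). Nonzero steps move
# one axis by exactly .JITTER_STEP_PX; the walk is folded into the jitter box.
.fixation_samples <- function(cx, cy, n) {
  if (n == 1L) return(cbind(cx, cy))
  move <- stats::runif(n - 1) < .JITTER_P_MOVE
  axis_x <- stats::runif(n - 1) < 0.5
  sgn <- sign(stats::runif(n - 1) - 0.5)
  dx <- ifelse(move & axis_x, sgn * .JITTER_STEP_PX, 0)
  dy <- ifelse(move & !axis_x, sgn * .JITTER_STEP_PX, 0)
  ox <- .fold(cumsum(c(0, dx)), .JITTER_BOX_PX)
  oy <- .fold(cumsum(c(0, dy)), .JITTER_BOX_PX)
  cbind(cx + ox, cy + oy)
}

# Saccade path from (x0,y0) to (x1,y1): triangular speed ramp
# (accelerate/decelerate, mean speed ~ peak/2) sampled at the frame rate.
.saccade_samples <- function(x0, y0, x1, y1, mean_speed_mm_s, pitch, dt_s) {
  d_mm <- sqrt((x1 - x0)^2 + (y1 - y0)^2) * pitch
  n <- max(2L, round(d_mm / mean_speed_mm_s / dt_s))
  w <- pmin(seq_len(n), rev(seq_len(n)))
  f <- cumsum(w / sum(w))
  cbind(x0 + f * (x1 - x0), y0 + f * (y1 - y0))
}

#' Simulate one digit-tracking trial
#'
#' Generates a 60 Hz finger trajectory over a sentence stimulus: left-to-right
#' first fixations on each word (landing position drawn around the profile's
#' mean for the word's length class), within-word refixations, fixation
#' phases of sampled duration with constant-magnitude low-speed jitter, and
#' saccade phases with a triangular speed ramp. Each saccade is independently
#' regressive (leftward) with probability `p_regressive`; a regressive
#' saccade revisits earlier text and does not advance the forward plan, so
#' the pooled regressive proportion equals `p_regressive` in expectation.
#'
#' @param profile A [reader_profile()].
#' @param stimulus A `stimulus_image` with at least one word box.
#' @param geometry A [screen_geometry()].
#' @param session Session index 1-6 (selects the profile's drift multipliers).
#' @param phase Training phase 1 or 2 (applies the profile's phase offsets).
#' @param seed Optional integer seed; a fixed seed reproduces the trajectory
#'   exactly.
#' @param subject_id,group,trial_id,exercise_type Identifier columns of the
#'   output.
#' @return A trajectory data.frame following the log schema (see
#'   [validate_trajectories()]).
#' @export
simulate_trial <- function(profile, stimulus, geometry, session = 1L,
                           phase = 1L, seed = NULL, subject_id = "S01",
                           group = 1L, trial_id = "t01",
                           exercise_type = "SE") {
  stopifnot(inherits(profile, "reader_profile"),
            inherits(stimulus, "stimulus_image"),
            session %in% 1:6, phase %in% 1:2)
  wb <- stimulus$word_boxes
  if (is.null(wb) || nrow(wb) == 0L) stop("stimulus has no word boxes", call. = FALSE)
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }

  drift <- profile$session_drift
  off <- if (phase == 2) profile$phase_offset else
    list(fixation_duration = 0, saccade_speed = 0, p_regressive = 0)
  dur_mean <- profile$fixation_duration_ms * drift$fixation_duration[session] +
    off$fixation_duration
  spd_mean <- profile$saccade_speed_mm_s * drift$saccade_speed[session] +
    off$saccade_speed
  p_reg <- min(max(profile$p_regressive * drift$p_regressive[session] +
                     off$p_regressive, 0), 1)
  amp <- profile$saccade_amplitude_mm * drift$amplitude[session]

  dt_ms <- 1000 / geometry$sampling_rate
  dt_s <- dt_ms / 1000
  pitch <- geometry$pixel_pitch

  # forward plan: first landing then refixations for each word, left to right
  tx <- numeric(); ty <- numeric()
  for (w in seq_len(nrow(wb))) {
    lclass <- word_length_class(wb$n_chars[w])
    lmean <- if (identical(lclass, "long")) profile$landing_mean_long else
      profile$landing_mean_short
    landing <- min(max(stats::rnorm(1, lmean, profile$landing_sd_chars), 0.2),
                   wb$n_chars[w] - 0.2)
    wx <- wb$origin_x[w] + landing * wb$char_width[w]
    n_refix <- stats::rpois(1, profile$refixation_rate * wb$n_chars[w])
    # planned refixations progress rightward from the landing so that only
    # the p_regressive draws produce leftward saccades
    lo <- min(landing + 0.4, wb$n_chars[w] - 0.4)
    hi <- wb$n_chars[w] - 0.3
    if (hi <= lo) n_refix <- 0L
    rx <- if (n_refix > 0)
      wb$origin_x[w] + sort(stats::runif(n_refix, lo, hi)) * wb$char_width[w]
    else numeric()
    xs <- c(wx, rx)
    tx <- c(tx, xs)
    ty <- c(ty, wb$origin_y[w] + wb$height[w] / 2 + stats::rnorm(length(xs), 0, 2))
  }
  left_edge <- min(wb$origin_x)

  draw_dur <- function() max(stats::rnorm(1, dur_mean,
                                          profile$fixation_duration_sd_ms), 120)
  draw_spd <- function() max(stats::rnorm(1, spd_mean,
                                          profile$saccade_speed_sd_mm_s), 15)
  fix_n <- function(dur) max(2L, round(dur / dt_ms) + 1L)

  pieces <- list()
  cur <- c(tx[1], ty[1])
  pieces[[1]] <- .fixation_samples(cur[1], cur[2], fix_n(draw_dur()))
  cur <- pieces[[1]][nrow(pieces[[1]]), ]
  i <- 2L
  n_targets <- length(tx)
  regress_left <- 3L * n_targets  # hard cap against pathological p_regressive
  while (i <= n_targets) {
    if (p_reg > 0 && regress_left > 0L && stats::runif(1) < p_reg &&
        cur[1] - left_edge > 4) {
      regress_left <- regress_left - 1L
      gx <- max(cur[1] - stats::runif(1, 0.5, 1.5) * amp / pitch, left_edge)
      gy <- ty[max(i - 1L, 1L)] + stats::rnorm(1, 0, 2)
      target <- c(gx, gy)
    } else {
      target <- c(tx[i], ty[i])
      i <- i + 1L
    }
    sac <- .saccade_samples(cur[1], cur[2], target[1], target[2],
                            draw_spd(), pitch, dt_s)
    fixc <- sac[nrow(sac), ]
    fix <- .fixation_samples(fixc[1], fixc[2], fix_n(draw_dur()))
    pieces[[length(pieces) + 1L]] <- sac
    pieces[[length(pieces) + 1L]] <- fix
    cur <- fix[nrow(fix), ]
  }

  xy <- do.call(rbind, pieces)
  n <- nrow(xy)
  pct <- pixels_to_percent(xy[, 1], xy[, 2], geometry)
  data.frame(subject_id = subject_id, group = group, phase = as.integer(phase),
             session = as.integer(session), trial_id = trial_id,
             exercise_type = exercise_type,
             t_ms = (seq_len(n) - 1L) * dt_ms,
             x_pct = pmin(pmax(pct$x_pct, 0), 100),
             y_pct = pmin(pmax(pct$y_pct, 0), 100),
             touching = TRUE,
             stringsAsFactors = FALSE)
}

#' Simulate an item-response vector for a reading assessment
#'
#' Item correctness is drawn independently with the profile's success
#' probability. Item counts follow the study's instruments: 85 for the
#' letter/syllable decoding list, 265 for the meaningless text, 45 for the
#' pseudoword list; the meaningful text uses a 150-word synthetic stand-in
#' (the real instrument's length is not modelled).
#'
#' @param profile A [reader_profile()] (or a bare success probability).
#' @param test Assessment label.
#' @param seed Optional integer seed.
#' @return Logical vector of item correctness.
#' @export
simulate_assessment <- function(profile,
                                test = c("letters_syllables",
                                         "meaningless_text",
                                         "meaningful_text", "pseudowords"),
                                seed = NULL) {
  test <- match.arg(test)
  p <- if (inherits(profile, "reader_profile")) profile$p_correct else profile
  stopifnot(p >= 0, p <= 1)
  n <- switch(test, letters_syllables = 85L, meaningless_text = 265L,
              meaningful_text = 150L, pseudowords = 45L)
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  stats::runif(n) < p
}

#' Cohort configuration for the simulator
#'
#' @param n_per_group Subjects per decoder group.
#' @param sessions Session indices simulated (default 1:6).
#' @param trials_per_session Sentence trials per session.
#' @param geometry A [screen_geometry()].
#' @param stimuli List of sentence stimuli cycled over trials.
#' @param good,poor [reader_profile()]s of the two groups.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration and this seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10L, sessions = 1:6,
                          trials_per_session = 3L,
                          geometry = screen_geometry(),
                          stimuli = default_sentence_set(geometry),
                          good = good_reader_profile(),
                          poor = poor_reader_profile(),
                          seed = 1L) {
  stopifnot(n_per_group >= 1L, all(sessions %in% 1:6),
            trials_per_session >= 1L, length(stimuli) >= 1L)
  structure(list(n_per_group = as.integer(n_per_group), sessions = sessions,
                 trials_per_session = as.integer(trials_per_session),
                 geometry = geometry, stimuli = stimuli,
                 good = good, poor = poor, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a full training cohort
#'
#' Generates one trajectory per subject x session x trial plus one decoding
#' assessment per subject. Half of each decoder group trains with
#' digit-tracking in phase 1, half in phase 2 (the crossover's two arms). The
#' subject table carries the true group labels and profiles for recovery
#' scoring.
#'
#' @param config A [cohort_config()].
#' @return A list of class `digitrace_cohort`: `trajectories` (one table, log
#'   schema), `subjects` (`subject_id`, `group_truth`, `phase`, `group`),
#'   `trials` (per-trial stimulus index), `assessments` (named list of logical
#'   item vectors), plus the `stimuli`, `geometry` and `config` used.
#' @examples
#' co <- simulate_cohort(cohort_config(n_per_group = 2, sessions = 1:2,
#'                                     trials_per_session = 1, seed = 7))
#' nrow(co$subjects)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)

  n <- config$n_per_group
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(2L * n)),
    group_truth = rep(c("good", "poor"), each = n),
    phase = rep(rep(1:2, length.out = n), 2L),
    stringsAsFactors = FALSE)
  subjects$group <- ifelse(subjects$phase == 1L, 1L, 2L)

  traj_list <- list(); trial_rows <- list()
  assessments <- vector("list", nrow(subjects))
  names(assessments) <- subjects$subject_id
  stim_i <- 0L
  for (s in seq_len(nrow(subjects))) {
    prof <- if (subjects$group_truth[s] == "good") config$good else config$poor
    for (sess in config$sessions) {
      for (tr in seq_len(config$trials_per_session)) {
        stim_i <- stim_i %% length(config$stimuli) + 1L
        tid <- sprintf("t%02d", tr)
        traj_list[[length(traj_list) + 1L]] <- simulate_trial(
          prof, config$stimuli[[stim_i]], config$geometry,
          session = sess, phase = subjects$phase[s],
          subject_id = subjects$subject_id[s], group = subjects$group[s],
          trial_id = tid)
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          subject_id = subjects$subject_id[s], phase = subjects$phase[s],
          session = sess, trial_id = tid, stimulus_index = stim_i,
          stringsAsFactors = FALSE)
      }
    }
    assessments[[s]] <- simulate_assessment(prof, "letters_syllables")
  }
  traj <- do.call(rbind, traj_list)
  class(traj) <- c("digitrace_trajectories", "data.frame")
  structure(list(trajectories = traj, subjects = subjects,
                 trials = do.call(rbind, trial_rows),
                 assessments = assessments, stimuli = config$stimuli,
                 geometry = config$geometry, config = config),
            class = "digitrace_cohort")
}

#' Run the analysis pipeline on a simulated or ingested cohort
#'
#' The full study pipeline: score the decoding assessments, median-split the
#' cohort into good and poor decoders, segment every trajectory with the
#' per-subject-session median-speed threshold, compute per-trial kinematics
#' and word-level metrics, and return analysis-ready tables.
#'
#' @param cohort A `digitrace_cohort` from [simulate_cohort()].
#' @return A list: `kinematics` (per-trial kinematics with `decoding`,
#'   `subject`, factors ready for [fit_kinematics_model()]), `word_metrics`
#'   (per trial x word), `scores`, `decoding` (median-split labels),
#'   `thresholds`, `fixations`, `saccades`.
#' @export
analyze_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "digitrace_cohort"))
  seg <- segment_cohort(cohort$trajectories, cohort$geometry)

  scores <- vapply(cohort$assessments, function(a)
    score_discontinuing_list(a, trim_warning = FALSE)$items_correct, 0L)
  decoding <- median_split(scores)

  kin <- seg$kinematics
  kin$subject <- kin$subject_id
  kin$decoding <- unname(decoding[kin$subject_id])
  kin$session <- as.integer(kin$session)
  kin$phase <- as.integer(kin$phase)

  wm_list <- list()
  fx <- seg$fixations
  if (!is.null(fx)) {
    key <- paste(fx$subject_id, fx$phase, fx$session, fx$trial_id, sep = "\r")
    tkey <- paste(cohort$trials$subject_id, cohort$trials$phase,
                  cohort$trials$session, cohort$trials$trial_id, sep = "\r")
    for (ti in seq_len(nrow(cohort$trials))) {
      rows <- fx[key == tkey[ti], , drop = FALSE]
      if (!nrow(rows)) next
      stim <- cohort$stimuli[[cohort$trials$stimulus_index[ti]]]
      wm <- word_fixation_metrics(rows, stim$word_boxes)
      wm$subject_id <- cohort$trials$subject_id[ti]
      wm$phase <- cohort$trials$phase[ti]
      wm$session <- cohort$trials$session[ti]
      wm$trial_id <- cohort$trials$trial_id[ti]
      wm_list[[length(wm_list) + 1L]] <- wm
    }
  }
  word_metrics <- if (length(wm_list)) do.call(rbind, wm_list) else NULL
  if (!is.null(word_metrics)) {
    word_metrics$decoding <- unname(decoding[word_metrics$subject_id])
  }

  list(kinematics = kin, word_metrics = word_metrics, scores = scores,
       decoding = decoding, thresholds = seg$thresholds,
       fixations = seg$fixations, saccades = seg$saccades)
}

#' Parameter recovery on one simulated cohort
#'
#' Simulates a cohort under the default (or supplied) study conditions, runs
#' the full pipeline, and returns the recovered quantities next to the
#' generator's truth: the good-poor saccade-speed contrast estimated by the
#' kinematics mixed model (marginal over session and phase), the mean digital
#' fixation duration, the pooled regressive-saccade proportion, and the mean
#' first-fixation landing position per word-length class.
#'
#' @param seed Integer seed for the cohort.
#' @param config Optional [cohort_config()]; its seed is replaced by `seed`.
#' @return A list: `speed_gap` (one-row contrast data.frame),
#'   `mean_fixation_duration_ms`, `p_regressive`, `landing_short`,
#'   `landing_long`, `truth` (the corresponding generative values), and the
#'   underlying `analysis`.
#' @export
cohort_parameter_recovery <- function(seed, config = NULL) {
  if (is.null(config)) config <- cohort_config(seed = seed)
  else config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  an <- analyze_cohort(cohort)

  fit <- fit_kinematics_model(an$kinematics, "mean_saccade_speed_mm_s")
  gap <- decoding_contrast(fit)

  kin <- an$kinematics
  wm <- an$word_metrics
  landing_short <- mean(wm$first_landing[wm$length_class == "short"],
                        na.rm = TRUE)
  landing_long <- mean(wm$first_landing[wm$length_class == "long"],
                       na.rm = TRUE)
  list(
    speed_gap = gap,
    mean_fixation_duration_ms = mean(kin$mean_fixation_duration_ms,
                                     na.rm = TRUE),
    p_regressive = sum(kin$n_regressive) / sum(kin$n_saccades),
    landing_short = landing_short,
    landing_long = landing_long,
    truth = list(
      speed_gap = config$good$saccade_speed_mm_s -
        config$poor$saccade_speed_mm_s,
      mean_fixation_duration_ms = (config$good$fixation_duration_ms +
                                     config$poor$fixation_duration_ms) / 2,
      p_regressive = (config$good$p_regressive + config$poor$p_regressive) / 2,
      landing_short = (config$good$landing_mean_short +
                         config$poor$landing_mean_short) / 2,
      landing_long = (config$good$landing_mean_long +
                        config$poor$landing_mean_long) / 2),
    analysis = an
  )
}
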