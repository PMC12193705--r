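#' Default pipeline configuration
#'
#' One list holding every decision knob of the pipeline, with the study's
#' protocol constants as defaults: screen 1920 x 1280 at 60 Hz, blur sigma
#' 20 px, dispersion limits 5.8/6.4 px, density bandwidth factor 0.4,
#' short/long word bounds 1-6/7-11 letters, decoding list of 85 items with
#' 5-error discontinuation, median-split ties to "poor", REML on for final
#' estimates.
#'
#' @param seed Integer seed for the simulated stages.
#' @param n_per_group,sessions,trials_per_session Cohort size knobs.
#' @param out_dir Output directory for [run_pipeline()].
#' @return A named list.
#' @export
pipeline_config <- function(seed = 1L, n_per_group = 4L, sessions = 1:6,
                            trials_per_session = 2L,
                            out_dir = tempfile("digitrace_run_")) {
  list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
       sessions = sessions, trials_per_session = as.integer(trials_per_session),
       out_dir = out_dir,
       geometry = list(width_px = 1920L, height_px = 1280L,
                       pixel_pitch = 0.135, viewing_distance = 300,
                       sampling_rate = 60),
       blur_sigma = 20, dispersion_px = c(5.8, 6.4),
       bandwidth_factor = 0.4, stop_run = 5L, max_items = 85L,
       tie_rule = "poor", REML = TRUE)
}

#' Run the study pipeline end to end
#'
#' Wires the stages in dependency order — simulate (or ingest) a cohort,
#' segment, per-trial kinematics, word metrics, density curves, assessment
#' scores and median split, kinematics mixed-model fits — writing CSV outputs
#' and a JSON run manifest (configuration snapshot, package version, seed,
#' decision knobs, and an MD5 hash of every output file). Re-running with the
#' same configuration reproduces every output bit for bit.
#'
#' @param config A [pipeline_config()] list, or a path to a JSON file holding
#'   one.
#' @param trajectories Optional pre-recorded trajectory table; when `NULL`
#'   a cohort is simulated from the config.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), trajectories = NULL) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  needed <- c("seed", "n_per_group", "sessions", "trials_per_session",
              "out_dir", "geometry", "bandwidth_factor", "tie_rule")
  missing_keys <- setdiff(needed, names(config))
  if (length(missing_keys)) {
    stop("pipeline config is missing: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$geometry$pixel_pitch)) {
    stop("pipeline config is missing geometry$pixel_pitch", call. = FALSE)
  }
  geom <- do.call(screen_geometry, config$geometry)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_cohort(cohort_config(
    n_per_group = config$n_per_group, sessions = config$sessions,
    trials_per_session = config$trials_per_session, geometry = geom,
    seed = config$seed))
  if (!is.null(trajectories)) {
    cohort$trajectories <- validate_trajectories(trajectories, geom)
  }

  an <- analyze_cohort(cohort)

  files <- c(trajectories = "trajectories.csv", kinematics = "kinematics.csv",
             fixations = "fixations.csv", saccades = "saccades.csv",
             word_metrics = "word_metrics.csv", scores = "scores.csv",
             densities = "density_curves.csv")
  paths <- file.path(config$out_dir, files)
  names(paths) <- names(files)
  write_trajectories(cohort$trajectories, paths["trajectories"])
  utils::write.csv(an$kinematics, paths["kinematics"], row.names = FALSE)
  utils::write.csv(an$fixations, paths["fixations"], row.names = FALSE)
  utils::write.csv(an$saccades, paths["saccades"], row.names = FALSE)
  utils::write.csv(an$word_metrics, paths["word_metrics"], row.names = FALSE)
  utils::write.csv(data.frame(subject_id = names(an$scores),
                              score = unname(an$scores),
                              decoding = unname(an$decoding[names(an$scores)])),
                   paths["scores"], row.names = FALSE)

  dens_rows <- list()
  wm <- an$word_metrics
  for (grp in c("good", "poor")) {
    sub <- wm[wm$decoding == grp & !is.na(wm$first_landing), , drop = FALSE]
    for (w in unique(sub$word)) {
      landings <- sub$first_landing[sub$word == w]
      if (length(unique(landings)) < 2L) next
      dc <- first_fixation_density(landings, group = grp,
                                   bandwidth_factor = config$bandwidth_factor)
      dens_rows[[length(dens_rows) + 1L]] <-
        data.frame(word = w, group = grp, x = dc$x, value = dc$value)
    }
  }
  utils::write.csv(do.call(rbind, dens_rows), paths["densities"],
                   row.names = FALSE)

  fit_speed <- fit_kinematics_model(an$kinematics, "mean_saccade_speed_mm_s",
                                    REML = isTRUE(config$REML))
  fit_dur <- fit_kinematics_model(an$kinematics, "mean_fixation_duration_ms",
                                  REML = isTRUE(config$REML))

  manifest <- list(
    package_version = as.character(utils::packageVersion("digitrace")),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")],
    knobs = list(tie_rule = config$tie_rule,
                 pixel_pitch = geom$pixel_pitch,
                 bandwidth_factor = config$bandwidth_factor,
                 REML = isTRUE(config$REML)),
    n_trajectories = nrow(cohort$trials),
    n_fixations = nrow(an$fixations),
    n_saccades = nrow(an$saccades),
    fits = list(
      saccade_speed = list(decoding_contrast = decoding_contrast(fit_speed)),
      fixation_duration = list(decoding_contrast = decoding_contrast(fit_dur))),
    outputs = lapply(as.list(paths), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
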