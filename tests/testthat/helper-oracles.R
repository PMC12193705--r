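# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: plain loops, naive recomputation.

small_geometry <- function() {
  screen_geometry(width_px = 400L, height_px = 300L, pixel_pitch = 0.135,
                  sampling_rate = 60)
}

# Brute-force segmentation: label every sample, then scan for streaks,
# splitting slow streaks whenever the running X/Y range reaches the limits.
oracle_segment <- function(trial, threshold, geometry,
                           dispersion_px = c(5.8, 6.4)) {
  n <- nrow(trial)
  px <- numeric(n); py <- numeric(n)
  for (i in seq_len(n)) {
    px[i] <- trial$x_pct[i] / 100 * geometry$width_px
    py[i] <- trial$y_pct[i] / 100 * geometry$height_px
  }
  lab <- character(n)
  for (i in seq_len(n)) {
    if (!trial$touching[i]) { lab[i] <- "gap"; next }
    if (i == 1L || !trial$touching[i - 1L]) { lab[i] <- "?"; next }
    d <- sqrt((px[i] - px[i - 1])^2 + (py[i] - py[i - 1])^2) *
      geometry$pixel_pitch
    v <- d / ((trial$t_ms[i] - trial$t_ms[i - 1]) / 1000)
    lab[i] <- if (v <= threshold * (1 + 1e-8)) "slow" else "fast"
  }
  # unresolved samples take the class of the next resolved sample in the same
  # touch streak, else the previous one
  for (i in seq_len(n)) {
    if (lab[i] != "?") next
    j <- i
    while (j <= n && lab[j] %in% c("?")) j <- j + 1L
    if (j <= n && lab[j] %in% c("slow", "fast")) { lab[i] <- lab[j]; next }
    j <- i
    while (j >= 1L && lab[j] %in% c("?")) j <- j - 1L
    lab[i] <- if (j >= 1L && lab[j] %in% c("slow", "fast")) lab[j] else "slow"
  }
  events <- list()
  i <- 1L
  while (i <= n) {
    if (lab[i] == "gap") { i <- i + 1L; next }
    j <- i
    while (j < n && lab[j + 1L] == lab[i]) j <- j + 1L
    if (lab[i] == "fast") {
      events[[length(events) + 1L]] <- list(type = "saccade", s = i, e = j)
    } else {
      s <- i
      while (s <= j) {
        e <- s
        while (e < j) {
          xs <- px[s:(e + 1L)]; ys <- py[s:(e + 1L)]
          if ((max(xs) - min(xs)) >= dispersion_px[1] ||
              (max(ys) - min(ys)) >= dispersion_px[2]) break
          e <- e + 1L
        }
        events[[length(events) + 1L]] <- list(type = "fixation", s = s, e = e)
        s <- e + 1L
      }
    }
    i <- j + 1L
  }
  events
}

# Random short trajectory mixing slow jitter, fast jumps and finger lifts.
random_trajectory <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:50, 1)
  t <- cumsum(c(0, runif(n - 1, 12, 22)))
  x <- numeric(n); y <- numeric(n)
  x[1] <- runif(1, 20, 80); y[1] <- runif(1, 20, 80)
  for (i in 2:n) {
    fast <- runif(1) < 0.35
    step <- if (fast) runif(1, 3, 12) else runif(1, 0, 0.6)
    ang <- runif(1, 0, 2 * pi)
    x[i] <- min(max(x[i - 1] + step * cos(ang), 0), 100)
    y[i] <- min(max(y[i - 1] + step * sin(ang), 0), 100)
  }
  data.frame(subject_id = "S1", group = 1L, phase = 1L, session = 1L,
             trial_id = "t1", exercise_type = "SE", t_ms = t,
             x_pct = x, y_pct = y,
             touching = runif(n) > 0.08, stringsAsFactors = FALSE)
}

# Compare package segmentation to the oracle event list.
expect_same_segmentation <- function(trial, threshold, geometry) {
  seg <- segment_trajectory(trial, threshold, geometry)
  ora <- oracle_segment(trial, threshold, geometry)
  got <- rbind(
    if (nrow(seg$fixations))
      data.frame(type = "fixation", s = seg$fixations$start_idx,
                 e = seg$fixations$end_idx),
    if (nrow(seg$saccades))
      data.frame(type = "saccade", s = seg$saccades$start_idx,
                 e = seg$saccades$end_idx))
  got <- got[order(got$s), , drop = FALSE]
  want <- data.frame(type = vapply(ora, `[[`, "", "type"),
                     s = vapply(ora, `[[`, 0L, "s"),
                     e = vapply(ora, `[[`, 0L, "e"))
  want <- want[order(want$s), , drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  identical(got, want)
}

# One-trial data.frame from bare pixel positions on a regular 60 Hz grid.
trial_from_px <- function(x_px, y_px, geometry, touching = TRUE) {
  n <- length(x_px)
  data.frame(subject_id = "S1", group = 1L, phase = 1L, session = 1L,
             trial_id = "t1", exercise_type = "SE",
             t_ms = (seq_len(n) - 1) * 1000 / geometry$sampling_rate,
             x_pct = x_px / geometry$width_px * 100,
             y_pct = y_px / geometry$height_px * 100,
             touching = rep_len(touching, n), stringsAsFactors = FALSE)
}

# Trial whose consecutive speeds (mm/s) follow `speeds` exactly, moving in x.
trial_from_speeds <- function(speeds, geometry) {
  dt <- 1 / geometry$sampling_rate
  steps_px <- speeds * dt / geometry$pixel_pitch
  trial_from_px(cumsum(c(50, steps_px)), rep(50, length(speeds) + 1), geometry)
}
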