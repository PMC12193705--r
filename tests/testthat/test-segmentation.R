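geom <- screen_geometry()  # study display

test_that("speeds combine Pythagoras, pixel pitch and the frame interval", {
  tr <- trial_from_px(c(0, 3), c(0, 4), geom)
  sp <- compute_speeds(tr, geom)$speed_mm_s
  expect_identical(sp[1], NA_real_)           # first sample carries no speed
  expect_equal(sp[2], 5 * 0.135 * 60)         # 40.5 mm/s
})

test_that("a stationary finger yields all-zero speeds, n samples yield n-1", {
  tr <- trial_from_px(rep(100, 25), rep(80, 25), geom)
  sp <- compute_speeds(tr, geom)$speed_mm_s
  expect_equal(sum(!is.na(sp)), 24L)
  expect_true(all(sp[-1] == 0))
})

test_that("pairs spanning a finger lift produce no speed value", {
  tr <- trial_from_px(seq(0, 90, by = 10), rep(50, 10), geom,
                      touching = c(rep(TRUE, 4), FALSE, rep(TRUE, 5)))
  sp <- compute_speeds(tr, geom)$speed_mm_s
  expect_true(is.na(sp[5]) && is.na(sp[6]))   # into and out of the lift
  expect_false(anyNA(sp[c(2:4, 7:10)]))
})

test_that("median threshold excludes nulls and matches sort-and-pick", {
  expect_equal(median_speed_threshold(c(0, 0, 1, 2, 3, 4, 5)), 3)
  expect_equal(median_speed_threshold(c(1, 2, 3, 4)), 2.5)
  expect_error(median_speed_threshold(c(0, 0, 0)), "degenerate")
  for (i in 1:25) {
    v <- c(rep(0, rpois(1, 3)), runif(rpois(1, 20) + 1, 0, 50), NA)
    pos <- sort(v[!is.na(v) & v > 0])
    n <- length(pos)
    oracle <- if (n %% 2 == 1) pos[(n + 1) / 2] else
      (pos[n / 2] + pos[n / 2 + 1]) / 2
    expect_equal(median_speed_threshold(v), oracle)
  }
})

test_that("streaks of slow and fast samples become alternating events", {
  tr <- trial_from_speeds(c(1, 1, 9, 9, 1, 1), geom)
  seg <- segment_trajectory(tr, 3, geom)
  expect_equal(nrow(seg$fixations), 2L)
  expect_equal(nrow(seg$saccades), 1L)
  # sample 1 has no speed and joins the following (slow) class: 3 + 2 + 2
  expect_equal(seg$fixations$n_samples, c(3L, 2L))
  expect_equal(seg$saccades$n_samples, 2L)
  expect_equal(seg$saccades$from_fixation, 1L)
  expect_equal(seg$saccades$to_fixation, 3L)
})

test_that("an all-slow trajectory is a single fixation and no saccade", {
  tr <- trial_from_speeds(rep(0.5, 20), geom)
  seg <- segment_trajectory(tr, 3, geom)
  expect_equal(nrow(seg$fixations), 1L)
  expect_equal(nrow(seg$saccades), 0L)
  kin <- trial_kinematics(seg$fixations, seg$saccades)
  expect_true(is.na(kin$proportion_regressive))  # missing, not 0
})

test_that("at-threshold samples join the fixation class", {
  tr <- trial_from_speeds(c(1, 3, 3, 9, 1), geom)
  seg <- segment_trajectory(tr, 3, geom)
  expect_equal(seg$fixations$n_samples[1], 4L)  # leading + 1 + two at-threshold
  expect_equal(seg$saccades$n_samples, 1L)
})

test_that("a saccade whose X does not advance is regressive", {
  # out-and-back fast excursion in x: last saccade sample x equals first
  x <- c(100, 100.5, 100, 180, 100.5, 100, 100.5)
  tr <- trial_from_px(x, rep(50, 7), geom)
  seg <- segment_trajectory(tr, 10, geom)
  expect_true(all(seg$saccades$direction == "regressive"))
  fwd <- trial_from_px(c(100, 100.5, 180, 260, 260.5, 260), rep(50, 6), geom)
  segf <- segment_trajectory(fwd, 10, geom)
  expect_equal(segf$saccades$direction, "progressive")
})

test_that("slow drift beyond the dispersion limits splits into several fixations", {
  # 0.5 px/frame drift: slow at a high threshold, 20 px total spread
  tr <- trial_from_px(seq(100, 120, by = 0.5), rep(50, 41), geom)
  seg <- segment_trajectory(tr, 1e3, geom)
  expect_gte(nrow(seg$fixations), 2L)
  # each piece respects the limits
  for (k in seq_len(nrow(seg$fixations))) {
    idx <- seg$fixations$start_idx[k]:seg$fixations$end_idx[k]
    expect_lt(diff(range(compute_speeds(tr, geom)$x_px[idx])), 5.8)
  }
})

test_that("barycenters lie inside the bounding box of member samples", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_trajectory(40)
    sp <- compute_speeds(tr, geom)$speed_mm_s
    th <- tryCatch(median_speed_threshold(sp), error = function(e) NULL)
    if (is.null(th)) next
    seg <- segment_trajectory(tr, th, geom)
    px <- compute_speeds(tr, geom)
    for (k in seq_len(nrow(seg$fixations))) {
      idx <- seg$fixations$start_idx[k]:seg$fixations$end_idx[k]
      expect_gte(seg$fixations$barycenter_x[k], min(px$x_px[idx]))
      expect_lte(seg$fixations$barycenter_x[k], max(px$x_px[idx]))
    }
  }
})

test_that("sample conservation: every sample is in exactly one event or a gap", {
  set.seed(77)
  for (i in 1:40) {
    tr <- random_trajectory()
    sp <- compute_speeds(tr, geom)$speed_mm_s
    th <- tryCatch(median_speed_threshold(sp), error = function(e) NULL)
    if (is.null(th)) next
    seg <- segment_trajectory(tr, th, geom)
    covered <- c(
      unlist(mapply(seq, seg$fixations$start_idx, seg$fixations$end_idx,
                    SIMPLIFY = FALSE)),
      unlist(mapply(seq, seg$saccades$start_idx, seg$saccades$end_idx,
                    SIMPLIFY = FALSE)))
    expect_equal(sort(c(covered, which(!tr$touching))), seq_len(nrow(tr)))
  }
})

test_that("events are strictly time-ordered and non-overlapping", {
  set.seed(13)
  for (i in 1:20) {
    tr <- random_trajectory()
    seg <- segment_trajectory(tr, 40, geom)
    ev <- rbind(seg$fixations[, c("start_idx", "end_idx")],
                seg$saccades[, c("start_idx", "end_idx")])
    ev <- ev[order(ev$start_idx), ]
    expect_true(all(ev$end_idx >= ev$start_idx))
    if (nrow(ev) > 1) expect_true(all(diff(ev$start_idx) > 0 &
                                        ev$start_idx[-1] > ev$end_idx[-nrow(ev)]))
  }
})

test_that("segmentation is invariant to monotone unit changes of the threshold", {
  set.seed(5)
  for (i in 1:10) {
    tr <- random_trajectory(35)
    sp <- compute_speeds(tr, geom)$speed_mm_s
    th <- tryCatch(median_speed_threshold(sp), error = function(e) NULL)
    if (is.null(th)) next
    seg_mm <- segment_trajectory(tr, th, geom)
    # same data expressed in px/frame: scale geometry so 1 px-frame = 1 mm/s
    g2 <- screen_geometry(width_px = geom$width_px, height_px = geom$height_px,
                          pixel_pitch = geom$pixel_pitch * 3,
                          sampling_rate = geom$sampling_rate)
    seg_scaled <- segment_trajectory(compute_speeds(tr, g2), th * 3, g2)
    expect_equal(seg_mm$fixations$start_idx, seg_scaled$fixations$start_idx)
    expect_equal(seg_mm$saccades$start_idx, seg_scaled$saccades$start_idx)
  }
})

test_that("trial kinematics aggregates follow their definitions", {
  fix <- data.frame(duration_ms = c(100, 300))
  sac <- data.frame(direction = c(rep("progressive", 6), rep("regressive", 2)),
                    length_mm = rep(2, 8), mean_speed_mm_s = rep(50, 8))
  kin <- trial_kinematics(fix, sac)
  expect_equal(kin$mean_fixation_duration_ms, 200)
  expect_equal(kin$proportion_regressive, 0.25)
  expect_equal(kin$n_saccades, kin$n_progressive + kin$n_regressive)
})

test_that("threshold sweep is consistent with segment() and has sane extremes", {
  tr <- trial_from_speeds(c(1, 1, 9, 9, 1, 1, 9, 1), geom)
  sw <- threshold_sweep(tr, c(0.01, 3, 100), geom)
  expect_equal(sw$n_fixations[sw$threshold == 3],
               nrow(segment_trajectory(tr, 3, geom)$fixations))
  # threshold below all speeds: everything is one saccade, no fixation
  expect_equal(sw$n_fixations[sw$threshold == 0.01], 0L)
  # threshold above all speeds: single fixation (dispersion permitting)
  expect_equal(sw$n_fixations[sw$threshold == 100], 1L)
  expect_error(threshold_sweep(tr, numeric(), geom), "no candidate")
})

test_that("threshold sweep counts match the brute-force oracle on a two-regime trace", {
  set.seed(8)
  speeds <- c(runif(10, 1, 3), runif(4, 40, 60), runif(10, 1, 3),
              runif(4, 40, 60), runif(10, 1, 3))
  tr <- trial_from_speeds(speeds, geom)
  cands <- c(0.5, 2, 10, 30, 70)
  sw <- threshold_sweep(tr, cands, geom)
  oracle_counts <- vapply(cands, function(th) {
    ev <- oracle_segment(tr, th, geom)
    sum(vapply(ev, `[[`, "", "type") == "fixation")
  }, 0L)
  expect_equal(sw$n_fixations, oracle_counts)
  # a threshold between the regimes separates the three slow stretches
  expect_equal(sw$n_fixations[sw$threshold == 10], 3L)
  # a threshold below every speed yields no fixation at all
  expect_equal(sw$n_fixations[sw$threshold == 0.5], 0L)
})
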