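geom <- screen_geometry(width_px = 1200L, height_px = 300L)
sentence <- render_text("La souris regarde le lapin", geom,
                        origin_x = 60, origin_y = 120, char_width = 20,
                        raster = FALSE)
wb <- sentence$word_boxes

fix_at <- function(x, y, t = seq_along(x) * 100) {
  data.frame(event = seq_along(x), start_t = t, end_t = t + 50,
             duration_ms = 50, barycenter_x = x, barycenter_y = y,
             n_samples = 5L, start_idx = 1L, end_idx = 5L)
}

test_that("word length classes use the inclusive 1-6 / 7-11 letter bounds", {
  expect_equal(word_length_class(nchar("lapin")), "short")
  expect_equal(word_length_class(nchar("regarde")), "long")
  expect_equal(word_length_class(6), "short")
  expect_equal(word_length_class(7), "long")
  expect_true(is.na(word_length_class(12)))
  expect_true(is.na(word_length_class(0)))
})

test_that("fixations are assigned to the word whose padded box contains them", {
  centers_x <- wb$origin_x + wb$n_chars * wb$char_width / 2
  cy <- wb$origin_y[1] + wb$height[1] / 2
  af <- assign_fixations(fix_at(centers_x, rep(cy, 5)), wb)
  expect_equal(af$word, wb$text)
  # 50 px below the line with 10 px vertical padding: unassigned
  below <- assign_fixations(fix_at(centers_x[3], wb$origin_y[1] + wb$height[1] + 50),
                            wb, pad_y = 10)
  expect_true(is.na(below$word_index))
})

test_that("revisits after intervening words start a new visit streak", {
  cx <- wb$origin_x + 10
  cy <- wb$origin_y[1] + 10
  seq_x <- c(cx[1], cx[1], cx[2], cx[1])  # w1, w1, w2, w1
  af <- assign_fixations(fix_at(seq_x, rep(cy, 4)), wb)
  expect_equal(af$visit, c(1L, 1L, 1L, 2L))
  wm <- word_fixation_metrics(fix_at(seq_x, rep(cy, 4)), wb)
  expect_equal(wm$n_visits[1], 2L)
  expect_equal(wm$n_fixations[1], 3L)
})

test_that("overlapping padded boxes are a configuration error", {
  expect_error(assign_fixations(fix_at(100, 130), wb, pad_x = 60),
               "overlap")
})

test_that("landing positions are continuous character units from the left edge", {
  box <- data.frame(origin_x = 500, char_width = 20, n_chars = 7)
  expect_equal(first_fixation_landing(box, 530), 1.5)
  expect_equal(first_fixation_landing(box, 500), 0)
  box5 <- data.frame(origin_x = 500, char_width = 20, n_chars = 5)
  expect_equal(first_fixation_landing(box5, 600), 5)      # right edge
  expect_equal(first_fixation_landing(box5, 620), 5)      # clipped
  expect_equal(first_fixation_landing(box5, 620, clip = FALSE), 6)
})

test_that("word metrics report the first fixation in time order", {
  cx <- wb$origin_x[3] + c(3.0, 1.0) * wb$char_width[3]
  cy <- wb$origin_y[1] + 10
  fx <- fix_at(cx, rep(cy, 2), t = c(500, 900))
  wm <- word_fixation_metrics(fx, wb)
  expect_equal(wm$first_landing[3], 3.0)
  expect_true(is.na(wm$first_landing[1]))  # unfixated word: missing
})

test_that("density bandwidth is 0.4 x the reference rule, hand-computed", {
  x <- c(1, 2, 3, 4, 5)
  by_hand <- 0.9 * min(sd(x), IQR(x) / 1.34) * 5^(-1 / 5)
  expect_equal(stats::bw.nrd0(x), by_hand)
  d <- first_fixation_density(x, group = "good", group_size = 10)
  expect_equal(attr(d, "bw"), 0.4 * by_hand)
})

test_that("density curves integrate to the group size and scale linearly", {
  set.seed(21)
  landings <- rnorm(10, 4.5, 0.2)
  d10 <- first_fixation_density(landings, group_size = 10)
  expect_equal(density_integral(d10), 10, tolerance = 0.05)
  expect_equal(d10$x[which.max(d10$value)], 4.5, tolerance = 0.1)
  d20 <- first_fixation_density(landings, group_size = 20)
  expect_equal(d20$value, 2 * d10$value)
  expect_error(first_fixation_density(rep(3, 5)), "distinct")
  expect_error(first_fixation_density(2.2), "distinct")
})

test_that("uniform landings over a word centre at half its length", {
  set.seed(99)
  box <- wb[wb$text == "regarde", ]
  n <- 500
  bx <- box$origin_x + runif(n, 0, box$n_chars) * box$char_width
  landings <- first_fixation_landing(box, bx)
  expect_equal(mean(landings), box$n_chars / 2, tolerance = 0.15)
})

test_that("per-word fixation counts increase with the refixation rate", {
  g <- screen_geometry()
  stim <- default_sentence_set(g)[[1]]
  counts <- vapply(c(0.02, 0.25), function(rate) {
    prof <- reader_profile(refixation_rate = rate, p_regressive = 0)
    tot <- 0
    for (s in 1:4) {
      tr <- simulate_trial(prof, stim, g, seed = 100 + s)
      sp <- compute_speeds(tr, g)
      seg <- segment_trajectory(sp, median_speed_threshold(sp), g)
      wm <- word_fixation_metrics(seg$fixations, stim$word_boxes)
      tot <- tot + sum(wm$n_fixations)
    }
    tot
  }, 0)
  expect_gt(counts[2], counts[1])
})
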