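geom <- screen_geometry(width_px = 800L, height_px = 240L,
                        pixel_pitch = 0.135)

test_that("render_text produces one box per word with monospace geometry", {
  img <- render_text("La souris regarde le lapin", geom,
                     origin_x = 40, origin_y = 100)
  expect_s3_class(img, "stimulus_image")
  expect_equal(nrow(img$word_boxes), 5L)
  expect_equal(img$word_boxes$n_chars[img$word_boxes$text == "regarde"], 7L)
  expect_equal(img$word_boxes$n_chars, nchar(img$word_boxes$text))
  expect_equal(dim(img$raster), c(240L, 800L))
  expect_gt(sum(img$raster), 0)
})

test_that("word box width is char_width times letter count and boxes do not overlap", {
  img <- render_text("lapin", geom, origin_x = 500 - 400, origin_y = 60,
                     char_width = 20, raster = FALSE)
  b <- img$word_boxes
  expect_equal(b$n_chars * b$char_width, 20 * 5)
  multi <- render_text("un deux trois", geom, origin_x = 20, origin_y = 60,
                       raster = FALSE)$word_boxes
  ends <- multi$origin_x + multi$n_chars * multi$char_width
  expect_true(all(ends[-3] <= multi$origin_x[-1]))
})

test_that("empty or overflowing text is rejected", {
  expect_error(render_text("", geom), "non-empty")
  expect_error(render_text("   ", geom), "non-empty")
  expect_error(render_text(strrep("a", 60), geom, origin_x = 10,
                           char_width = 20), "overflow")
})

test_that("blurring preserves geometry, mass, and the degenerate cases", {
  img <- render_text("bora muti", geom, origin_x = 60, origin_y = 100)
  same <- blur_image(img, 0)
  expect_identical(same$raster, img$raster)
  flat <- img
  flat$raster <- matrix(0.5, nrow(img$raster), ncol(img$raster))
  blurred_flat <- blur_image(flat, 5)
  expect_equal(blurred_flat$raster, flat$raster, tolerance = 1e-10)
  blurred <- blur_image(img, 5)
  expect_identical(blurred$word_boxes, img$word_boxes)
  expect_equal(sum(blurred$raster), sum(img$raster), tolerance = 1e-6)
  expect_error(blur_image(img, -1), "non-negative")
})

test_that("an impulse blurs to the 2-D Gaussian kernel", {
  g2 <- screen_geometry(width_px = 121L, height_px = 121L)
  img <- render_text("a", g2, origin_x = 10, origin_y = 10)
  img$raster <- matrix(0, 121, 121)
  img$raster[61, 61] <- 1
  out <- blur_image(img, 6)$raster
  d2 <- outer((1:121 - 61)^2, (1:121 - 61)^2, `+`)
  kernel <- exp(-d2 / (2 * 6^2)) / (2 * pi * 6^2)
  expect_lt(max(abs(out - kernel)), 0.01 * max(kernel))
})

test_that("the unblur window restores the original only around the finger", {
  img <- render_text("bora muti", geom, origin_x = 60, origin_y = 100)
  blurred <- blur_image(img, 8)
  b <- img$word_boxes[1, ]
  cx <- b$origin_x + b$n_chars * b$char_width / 2
  cy <- b$origin_y + b$height / 2
  frame <- unblur_window(blurred, img, c(cx, cy), radius = 40)
  expect_equal(frame[round(cy), round(cx)], img$raster[round(cy), round(cx)])
  far <- frame[abs(row(frame) - cy) > 45 | abs(col(frame) - cx) > 45]
  ref <- blurred$raster[abs(row(frame) - cy) > 45 | abs(col(frame) - cx) > 45]
  expect_identical(far, ref)
  # idempotent for a fixed finger position
  frame2 <- unblur_window(blurred, img, c(cx, cy), radius = 40)
  expect_identical(frame, frame2)
})

test_that("degenerate unblur windows fall back to the blurred frame", {
  img <- render_text("bora", geom, origin_x = 60, origin_y = 100)
  blurred <- blur_image(img, 8)
  expect_identical(unblur_window(blurred, img, c(200, 120), radius = 0),
                   blurred$raster)
  expect_identical(unblur_window(blurred, img, c(-50, 120), radius = 40),
                   blurred$raster)
  expect_identical(unblur_window(blurred, img, c(5000, 120), radius = 40),
                   blurred$raster)
})
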