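#' Lay out and render text as a stimulus image with word geometry
#'
#' Places whitespace-delimited words on the screen under a monospace
#' assumption, so character positions are affine in letter index: word `w`
#' occupies `[origin_x, origin_x + n_chars * char_width)` horizontally. The
#' returned word boxes anchor all landing-position and refixation metrics.
#'
#' Glyphs are drawn schematically (a deterministic per-character dot pattern):
#' the scientific content of a stimulus is its word geometry and its blur
#' state, not its typeface.
#'
#' @param text A non-empty string; `\n` starts a new line.
#' @param geometry A [screen_geometry()].
#' @param origin_x,origin_y Top-left of the text block, px.
#' @param char_width,char_height Monospace cell size, px.
#' @param line_spacing Baseline-to-baseline distance, px.
#' @param raster If `FALSE`, skip drawing and return geometry only (fast path
#'   used by the simulator).
#' @return An object of class `stimulus_image`: a list with `raster` (numeric
#'   `height_px x width_px` matrix in \[0,1\], ink = 1, or `NULL`),
#'   `word_boxes` (data.frame: `text`, `n_chars`, `origin_x`, `origin_y`,
#'   `char_width`, `height`, `line_index`), `blur_sigma` (0 for a sharp
#'   render) and `geometry`.
#' @examples
#' img <- render_text("La souris regarde le lapin",
#'                    screen_geometry(width_px = 800, height_px = 200),
#'                    origin_x = 40, origin_y = 80)
#' img$word_boxes$n_chars
#' @export
render_text <- function(text, geometry, origin_x = 200, origin_y = 600,
                        char_width = 20, char_height = 32,
                        line_spacing = 1.8 * char_height, raster = TRUE) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("`text` must be a non-empty string", call. = FALSE)
  }
  stopifnot(inherits(geometry, "screen_geometry"),
            char_width > 0, char_height > 0)

  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  boxes <- list()
  for (li in seq_along(lines)) {
    words <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    x <- origin_x
    y <- origin_y + (li - 1L) * line_spacing
    for (w in words) {
      nc <- nchar(w)
      boxes[[length(boxes) + 1L]] <- data.frame(
        text = w, n_chars = nc, origin_x = x, origin_y = y,
        char_width = char_width, height = char_height, line_index = li,
        stringsAsFactors = FALSE)
      x <- x + (nc + 1L) * char_width  # one blank cell between words
    }
    if (x - char_width > geometry$width_px ||
        y + char_height > geometry$height_px) {
      stop(sprintf("text overflows the %d x %d raster on line %d",
                   geometry$width_px, geometry$height_px, li), call. = FALSE)
    }
  }
  word_boxes <- do.call(rbind, boxes)

  ras <- NULL
  if (raster) {
    ras <- matrix(0, nrow = geometry$height_px, ncol = geometry$width_px)
    for (bi in seq_len(nrow(word_boxes))) {
      b <- word_boxes[bi, ]
      chars <- strsplit(b$text, "")[[1]]
      for (ci in seq_along(chars)) {
        x0 <- b$origin_x + (ci - 1L) * b$char_width
        ras <- .draw_glyph(ras, chars[ci], x0, b$origin_y,
                           b$char_width, b$height)
      }
    }
  }

  structure(list(raster = ras, word_boxes = word_boxes, blur_sigma = 0,
                 geometry = geometry),
            class = "stimulus_image")
}

# Deterministic 5x7 dot-matrix pseudo-glyph derived from the character code
# through a small Lehmer generator (kept in exact double arithmetic).
.draw_glyph <- function(ras, ch, x0, y0, w, h) {
  x <- (utf8ToInt(ch) %% 2147483646) + 1
  bits <- integer(35)
  for (k in 1:35) {
    x <- (x * 16807) %% 2147483647
    bits[k] <- as.integer(x %% 2)
  }
  grid <- matrix(bits, nrow = 7, ncol = 5)
  grid[, 1] <- 1L  # left stem keeps every glyph connected and inked
  cw <- w / 5; chh <- h / 7
  for (r in 1:7) for (c in 1:5) {
    if (grid[r, c] == 1L) {
      rows <- max(1L, round(y0 + (r - 1) * chh)):min(nrow(ras), round(y0 + r * chh - 1))
      cols <- max(1L, round(x0 + (c - 1) * cw)):min(ncol(ras), round(x0 + c * cw - 1))
      ras[rows, cols] <- 1
    }
  }
  ras
}

#' Gaussian-blur a stimulus image
#'
#' Blurs the raster with an isotropic Gaussian kernel (standard deviation
#' `sigma` pixels; the study display used 20 px) while leaving the word
#' geometry untouched. Convolution is delegated to [EBImage::gblur()] with
#' circular boundary handling, which conserves total image mass.
#'
#' @param image A `stimulus_image` with a non-`NULL` raster.
#' @param sigma Blur standard deviation, px (>= 0; 0 returns the input).
#' @return A `stimulus_image` with blurred raster and `blur_sigma = sigma`.
#' @export
blur_image <- function(image, sigma = 20) {
  stopifnot(inherits(image, "stimulus_image"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(image$raster)) stop("image has no raster to blur", call. = FALSE)
  out <- image
  if (sigma > 0) {
    out$raster <- EBImage::gblur(image$raster, sigma = sigma)
  }
  out$blur_sigma <- sigma
  out
}

#' Compose a finger-contingent unblur frame
#'
#' The digit-tracking display shows the blurred stimulus everywhere except in
#' a window around the finger, where the original sharp text appears — the
#' crowding-free "fovea". The window is circular with a hard edge; its default
#' radius is 2 degrees of visual angle at the configured viewing distance
#' (about 78 px on the study display).
#'
#' @param blurred,original Two `stimulus_image`s sharing the same geometry.
#' @param finger_xy Numeric length-2, finger position in px. Positions outside
#'   the raster yield the fully blurred frame.
#' @param radius Window radius in px; `NULL` uses 2 degrees of visual angle.
#' @return The composed frame raster (numeric matrix).
#' @export
unblur_window <- function(blurred, original, finger_xy, radius = NULL) {
  stopifnot(inherits(blurred, "stimulus_image"),
            inherits(original, "stimulus_image"))
  if (!identical(dim(blurred$raster), dim(original$raster))) {
    stop("blurred and original images do not share geometry", call. = FALSE)
  }
  geom <- blurred$geometry
  if (is.null(radius)) radius <- degrees_to_pixels(2, geom)
  stopifnot(radius >= 0)
  frame <- blurred$raster
  fx <- finger_xy[1]; fy <- finger_xy[2]
  if (is.na(fx) || is.na(fy) ||
      fx < 0 || fx > geom$width_px || fy < 0 || fy > geom$height_px ||
      radius == 0) {
    return(frame)
  }
  rows <- max(1L, ceiling(fy - radius)):min(nrow(frame), floor(fy + radius))
  cols <- max(1L, ceiling(fx - radius)):min(ncol(frame), floor(fx + radius))
  if (length(rows) == 0L || length(cols) == 0L) return(frame)
  dy2 <- (rows - fy)^2
  dx2 <- (cols - fx)^2
  inside <- outer(dy2, dx2, `+`) <= radius^2
  sub <- frame[rows, cols, drop = FALSE]
  orig <- original$raster[rows, cols, drop = FALSE]
  sub[inside] <- orig[inside]
  frame[rows, cols] <- sub
  frame
}
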