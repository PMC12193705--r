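#' Screen geometry of the digit-tracking display
#'
#' Describes the touchscreen on which stimuli are shown and finger positions
#' are logged. The study display is a 1920 x 1280 tablet sampled at 60 Hz and
#' viewed from 300 mm. Finger positions are logged as percent-of-screen and
#' converted to pixels and millimetres through this object, so every
#' millimetre-valued kinematic quantity (saccade length, speed) depends on
#' `pixel_pitch`.
#'
#' The physical pixel pitch is not part of the logs; the default 0.135 mm/px
#' corresponds to a 12.3-inch 3:2 panel at 1920 x 1280 (see
#' [pixel_pitch_from_panel()]).
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param pixel_pitch Physical size of one pixel, mm.
#' @param viewing_distance Eye-screen distance, mm.
#' @param sampling_rate Touch sampling rate, Hz.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' percent_to_pixels(50, 50, geom)
#' @export
screen_geometry <- function(width_px = 1920L, height_px = 1280L,
                            pixel_pitch = 0.135, viewing_distance = 300,
                            sampling_rate = 60) {
  stopifnot(width_px > 0, height_px > 0, sampling_rate > 0)
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L ||
      is.na(pixel_pitch) || pixel_pitch <= 0) {
    stop("`pixel_pitch` must be a single positive number (mm per pixel)",
         call. = FALSE)
  }
  if (viewing_distance <= 0) stop("`viewing_distance` must be positive", call. = FALSE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_pitch = pixel_pitch, viewing_distance = viewing_distance,
         sampling_rate = sampling_rate),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.4g mm/px, %g Hz, viewed at %g mm\n",
              x$width_px, x$height_px, x$pixel_pitch, x$sampling_rate,
              x$viewing_distance))
  invisible(x)
}

#' Pixel pitch of a panel from its diagonal
#'
#' Helper for configuring [screen_geometry()] when only the marketing diagonal
#' of the display is known. Assumes square pixels.
#'
#' @param diagonal_mm Panel diagonal in millimetres (1 inch = 25.4 mm).
#' @param width_px,height_px Native resolution.
#' @return Pixel pitch in mm/px.
#' @examples
#' pixel_pitch_from_panel(12.3 * 25.4, 1920, 1280) # ~0.135 mm/px
#' @export
pixel_pitch_from_panel <- function(diagonal_mm, width_px, height_px) {
  stopifnot(diagonal_mm > 0, width_px > 0, height_px > 0)
  diagonal_mm / sqrt(width_px^2 + height_px^2)
}

#' Convert percent-of-screen coordinates to pixels
#'
#' Finger positions are logged as percent of screen width (X) and height (Y).
#' The convention is continuous, origin top-left, x rightward, y downward:
#' (100, 100) maps to (`width_px`, `height_px`).
#'
#' @param x_pct,y_pct Numeric vectors in \[0, 100\].
#' @param geometry A [screen_geometry()].
#' @return A data.frame with columns `x_px`, `y_px`.
#' @export
percent_to_pixels <- function(x_pct, y_pct, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  data.frame(x_px = x_pct / 100 * geometry$width_px,
             y_px = y_pct / 100 * geometry$height_px)
}

#' Convert pixel coordinates back to percent-of-screen
#'
#' Inverse of [percent_to_pixels()].
#'
#' @inheritParams percent_to_pixels
#' @param x_px,y_px Numeric vectors of pixel coordinates.
#' @return A data.frame with columns `x_pct`, `y_pct`.
#' @export
pixels_to_percent <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  data.frame(x_pct = x_px / geometry$width_px * 100,
             y_pct = y_px / geometry$height_px * 100)
}

#' Convert a pixel displacement to millimetres
#'
#' @param delta_px Displacement(s) in pixels.
#' @param geometry A [screen_geometry()]; its `pixel_pitch` must be set.
#' @return Displacement in mm.
#' @examples
#' pixels_to_mm(100, screen_geometry(pixel_pitch = 0.135)) # 13.5 mm
#' @export
pixels_to_mm <- function(delta_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  delta_px * geometry$pixel_pitch
}

#' Visual angle subtended on screen, in pixels
#'
#' Used for the default size of the finger-contingent unblur window (about the
#' foveal 2 degrees).
#'
#' @param degrees Visual angle in degrees.
#' @param geometry A [screen_geometry()].
#' @return Extent in pixels.
#' @export
degrees_to_pixels <- function(degrees, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mm <- 2 * geometry$viewing_distance * tan(degrees / 2 * pi / 180)
  mm / geometry$pixel_pitch
}
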