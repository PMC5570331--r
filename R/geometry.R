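#' Screen geometry descriptor
#'
#' Bundles the physical dimensions, pixel resolution and viewing distance of
#' the presentation screen. All gaze computations that convert between pixels
#' and degrees of visual angle take such an object.
#'
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @param width_px,height_px Screen resolution in pixels.
#' @param distance_mm Viewing distance (eye to screen) in millimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(516.9, 323.1, 1920, 1200, 500)
#' pixels_to_degrees(1200, "horizontal", geom)
#' @export
screen_geometry <- function(width_mm, height_mm, width_px, height_px,
                            distance_mm) {
  vals <- c(width_mm = width_mm, height_mm = height_mm,
            width_px = width_px, height_px = height_px,
            distance_mm = distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid geometry: all screen_geometry fields must be finite and strictly positive")
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("screen_geometry: %.1f x %.1f mm, %d x %d px, distance %.0f mm\n",
              x$width_mm, x$height_mm, x$width_px, x$height_px, x$distance_mm))
  cat(sprintf("  pixel pitch: %.4f x %.4f mm/px\n",
              x$width_mm / x$width_px, x$height_mm / x$height_px))
  invisible(x)
}

#' Default screen geometry of the reference setup
#'
#' 24-inch screen, 516.9 x 323.1 mm, 1920 x 1200 px, viewed from 500 mm.
#' A 1200 x 900 px stimulus then subtends 35.81 x 27.24 degrees.
#'
#' @return A `screen_geometry` object.
#' @export
default_geometry <- function() {
  screen_geometry(516.9, 323.1, 1920, 1200, 500)
}

pixel_pitch <- function(geom, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") geom$width_mm / geom$width_px
  else geom$height_mm / geom$height_px
}

#' Convert a pixel extent to degrees of visual angle
#'
#' Uses the exact full-angle formula `2 * atan(s / (2 d))` where `s` is the
#' physical extent of the pixels and `d` the viewing distance, not the
#' small-angle approximation.
#'
#' @param extent_px Extent in pixels (vectorised, must be `>= 0`).
#' @param axis `"horizontal"` or `"vertical"` (pixel pitch differs per axis).
#' @param geom A [screen_geometry()].
#'
#' @return Visual angle in degrees.
#' @seealso [degrees_to_pixels()] for the inverse.
#' @export
pixels_to_degrees <- function(extent_px, axis = c("horizontal", "vertical"),
                              geom = default_geometry()) {
  axis <- match.arg(axis)
  stopifnot(inherits(geom, "screen_geometry"))
  if (any(extent_px < 0, na.rm = TRUE)) stop("extent_px must be >= 0")
  pitch <- pixel_pitch(geom, axis)
  2 * atan((extent_px * pitch / 2) / geom$distance_mm) * 180 / pi
}

#' Convert degrees of visual angle to a pixel extent
#'
#' Exact inverse of [pixels_to_degrees()].
#'
#' @param extent_deg Visual angle in degrees (vectorised).
#' @inheritParams pixels_to_degrees
#' @return Extent in pixels.
#' @export
degrees_to_pixels <- function(extent_deg, axis = c("horizontal", "vertical"),
                              geom = default_geometry()) {
  axis <- match.arg(axis)
  stopifnot(inherits(geom, "screen_geometry"))
  pitch <- pixel_pitch(geom, axis)
  2 * geom$distance_mm * tan(extent_deg * pi / 180 / 2) / pitch
}

# Angular position (deg) of a pixel coordinate relative to screen center.
# Used by the event detector to express gaze positions in degrees before
# differentiating; the tangent mapping is exact for off-center positions.
position_to_degrees <- function(px, axis = c("horizontal", "vertical"),
                                geom = default_geometry()) {
  axis <- match.arg(axis)
  pitch <- pixel_pitch(geom, axis)
  center <- if (axis == "horizontal") (geom$width_px - 1) / 2 else (geom$height_px - 1) / 2
  atan(((px - center) * pitch) / geom$distance_mm) * 180 / pi
}
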