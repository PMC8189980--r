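#' Screen geometry for degree/pixel conversion
#'
#' Describes the presentation screen and viewing distance used to convert
#' between degrees of visual angle and pixels. Defaults correspond to a
#' 23-inch 1920 x 1080 display viewed from 60 cm.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_in Physical diagonal in inches.
#' @param distance_cm Viewing distance in centimetres.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_per_degree(geom)
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_in = 23, distance_cm = 60) {
  stopifnot(width_px > 0, height_px > 0, diagonal_in > 0, distance_cm > 0)
  cm_per_px <- diagonal_in * 2.54 / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_in = diagonal_in, distance_cm = distance_cm,
         cm_per_px = cm_per_px),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f in diagonal, %.0f cm viewing distance (%.2f px/deg)\n",
              x$width_px, x$height_px, x$diagonal_in, x$distance_cm,
              pixels_per_degree(x)))
  invisible(x)
}

#' Pixels subtended by one degree of visual angle
#'
#' Uses the linear small-angle convention: the on-screen extent of 1 degree
#' at the viewing distance, divided by the physical pixel pitch.
#'
#' @param geometry A [screen_geometry()].
#' @return Pixels per degree (scalar, > 0).
#' @export
pixels_per_degree <- function(geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  geometry$distance_cm * tan(pi / 180) / geometry$cm_per_px
}

#' Convert degrees of visual angle to pixels (and back)
#'
#' Linear conversion `px = deg * pixels_per_degree(geometry)`; suitable for
#' the central screen region where stimuli are presented.
#'
#' @param deg,px Numeric vector of extents.
#' @param geometry A [screen_geometry()].
#' @return Numeric vector of the same length.
#' @export
degrees_to_pixels <- function(deg, geometry) {
  deg * pixels_per_degree(geometry)
}

#' @rdname degrees_to_pixels
#' @export
pixels_to_degrees <- function(px, geometry) {
  px / pixels_per_degree(geometry)
}
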