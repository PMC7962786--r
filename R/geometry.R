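# Screen / image geometry and visual-angle conversion.
#
# Convention used throughout the package: origin at the top-left of the
# screen, x rightward, y downward, 0-based pixel indices, a position refers
# to the centre of its pixel.

#' Screen geometry
#'
#' Describes the display used for stimulus presentation. The default values
#' correspond to a 1920 x 1080 px monitor of 51.5 x 29 cm viewed at 60 cm,
#' a typical desktop eye-tracking setup.
#'
#' A square-pixel assumption is *checked*, not silently assumed: the
#' horizontal and vertical cm-per-px must agree within 1%.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_cm,height_cm physical display size in cm.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            width_cm = 51.5, height_cm = 29,
                            viewing_distance_cm = 60) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_cm = width_cm, height_cm = height_cm,
            viewing_distance_cm = viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen_geometry fields must be strictly positive and finite")
  }
  cmppx_h <- width_cm / width_px
  cmppx_v <- height_cm / height_px
  if (abs(cmppx_h - cmppx_v) / cmppx_h > 0.01) {
    warning(sprintf(
      "non-square pixels: horizontal %.5f vs vertical %.5f cm/px differ by more than 1%%",
      cmppx_h, cmppx_v))
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' Pixels per degree of visual angle
#'
#' Computes how many pixels subtend one degree of visual angle at the screen
#' centre, using the horizontal axis: `1 / atan(cm_per_px / distance)` with
#' the angle expressed in degrees. A single isotropic scale is used; the
#' vertical axis serves only as a consistency check (see
#' [screen_geometry()]). Eccentricity-dependent correction is omitted, which
#' is negligible for typical monitor geometries.
#'
#' @param geom a [screen_geometry()].
#' @return pixels per degree (scalar).
#' @export
px_per_degree <- function(geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  cm_per_px <- geom$width_cm / geom$width_px
  deg_per_px <- atan2(cm_per_px, geom$viewing_distance_cm) * 180 / pi
  1 / deg_per_px
}

#' Convert between pixels and degrees of visual angle
#'
#' Linear small-angle conversion using the isotropic scale from
#' [px_per_degree()]; self-inverse to machine precision.
#'
#' @param v values to convert.
#' @param geom a [screen_geometry()].
#' @return converted values.
#' @export
px_to_deg <- function(v, geom) v / px_per_degree(geom)

#' @rdname px_to_deg
#' @export
deg_to_px <- function(v, geom) v * px_per_degree(geom)

#' Image placement on screen
#'
#' Position of the stimulus-image rectangle on the display. By default the
#' image is centred on the screen (stimuli are presented in front of a
#' uniform background with no offset).
#'
#' @param width_px,height_px image size in pixels (max 1300 x 800 for the
#'   default stimulus set).
#' @param geom a [screen_geometry()] used for centring.
#' @param origin_x_px,origin_y_px top-left corner of the image on screen;
#'   defaults centre the image.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(width_px = 1300, height_px = 800,
                        geom = screen_geometry(),
                        origin_x_px = NULL, origin_y_px = NULL) {
  if (width_px <= 0 || height_px <= 0) stop("image dimensions must be positive")
  if (is.null(origin_x_px)) origin_x_px <- (geom$width_px - width_px) / 2
  if (is.null(origin_y_px)) origin_y_px <- (geom$height_px - height_px) / 2
  if (origin_x_px < 0 || origin_y_px < 0 ||
      origin_x_px + width_px > geom$width_px ||
      origin_y_px + height_px > geom$height_px) {
    stop("image rectangle must lie within screen bounds")
  }
  structure(list(origin_x_px = origin_x_px, origin_y_px = origin_y_px,
                 width_px = width_px, height_px = height_px),
            class = "image_frame")
}

#' Test whether points fall inside an image frame
#'
#' @param x_px,y_px screen coordinates.
#' @param frame an [image_frame()].
#' @return logical vector.
#' @export
in_frame <- function(x_px, y_px, frame) {
  stopifnot(inherits(frame, "image_frame"))
  !is.na(x_px) & !is.na(y_px) &
    x_px >= frame$origin_x_px & x_px < frame$origin_x_px + frame$width_px &
    y_px >= frame$origin_y_px & y_px < frame$origin_y_px + frame$height_px
}
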