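#' Visual angle subtended by a flat extent
#'
#' Converts a physical extent on a flat surface (e.g. a monitor) viewed
#' head-on at a given distance into the visual angle it subtends,
#' \eqn{2 \arctan(\mathrm{extent}/2d)}.
#'
#' @param extent_cm Physical extent in cm (non-negative).
#' @param distance_cm Viewing distance in cm (strictly positive).
#' @return Visual angle in degrees.
#' @examples
#' visual_angle(40.4, 7)   # horizontal extent of a 40.4 cm screen at 7 cm
#' @export
visual_angle <- function(extent_cm, distance_cm) {
  if (any(!is.finite(distance_cm)) || any(distance_cm <= 0)) {
    stop("invalid geometry: `distance_cm` must be finite and > 0")
  }
  if (any(!is.finite(extent_cm)) || any(extent_cm < 0)) {
    stop("invalid geometry: `extent_cm` must be finite and >= 0")
  }
  2 * atan2(extent_cm / 2, distance_cm) * 180 / pi
}

#' Screen geometry of the stimulus display
#'
#' Bundles the physical display parameters used for angular conversions.
#' Defaults describe a 40.4 x 30.2 cm CRT viewed at 7 cm (subtending about
#' 142 degrees horizontally), refreshing at 85 Hz with a mean luminance of
#' 27.1 cd/m^2.
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param viewing_distance_cm Eye-to-screen distance in cm.
#' @param frame_rate_hz Monitor refresh rate in Hz.
#' @param mean_luminance_cdm2 Mean luminance in cd/m^2.
#' @return An object of class `screen_geometry` with the fields above plus
#'   the derived `angular_extent_deg`.
#' @export
screen_geometry <- function(width_cm = 40.4, height_cm = 30.2,
                            viewing_distance_cm = 7,
                            frame_rate_hz = 85,
                            mean_luminance_cdm2 = 27.1) {
  stopifnot(width_cm > 0, height_cm > 0, frame_rate_hz > 0,
            mean_luminance_cdm2 >= 0)
  if (viewing_distance_cm <= 0) stop("invalid geometry: viewing distance must be > 0")
  structure(
    list(
      width_cm = width_cm,
      height_cm = height_cm,
      viewing_distance_cm = viewing_distance_cm,
      angular_extent_deg = visual_angle(width_cm, viewing_distance_cm),
      frame_rate_hz = frame_rate_hz,
      mean_luminance_cdm2 = mean_luminance_cdm2
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %.1f x %.1f cm at %.1f cm (%.1f deg wide), %g Hz, %.1f cd/m^2\n",
    x$width_cm, x$height_cm, x$viewing_distance_cm,
    x$angular_extent_deg, x$frame_rate_hz, x$mean_luminance_cdm2
  ))
  invisible(x)
}
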