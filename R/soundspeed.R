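# Speed-of-sound distortion correction for curvilinear probes.
#
# Scanners convert echo time to depth assuming c_cal (1540 m/s for soft
# tissue). When the coupling medium is water at room temperature the true
# speed c_a is lower, so every segmented point appears too deep along its
# scan line. The ray model treats each scan line as a ray from the arc
# center of the curvilinear footprint: the ray segment beyond the footprint
# (D_im - R) scales by c_a / c_cal.

#' Speed of sound in pure water from temperature
#'
#' Fifth-order polynomial fit for distilled water at atmospheric pressure
#' (Marczak 1997, J. Acoust. Soc. Am. 102:2776-2779), valid on 0-95 degrees
#' Celsius:
#' c(T) = 1402.385 + 5.038813 T - 5.799136e-2 T^2 + 3.287156e-4 T^3
#'        - 1.398845e-6 T^4 + 2.787860e-9 T^5.
#'
#' @param temperature_C water temperature in degrees Celsius, within [0, 95].
#' @return Speed of sound in m/s.
#' @examples
#' water_sound_speed(20) # ~1482.4 m/s
#' @export
water_sound_speed <- function(temperature_C) {
  if (any(!is.finite(temperature_C)) ||
      any(temperature_C < 0) || any(temperature_C > 95))
    stop("temperature must be within [0, 95] degrees Celsius")
  tt <- temperature_C
  1.402385e3 + 5.038813 * tt - 5.799136e-2 * tt^2 + 3.287156e-4 * tt^3 -
    1.398845e-6 * tt^4 + 2.787860e-9 * tt^5
}

#' Curvilinear probe footprint geometry
#'
#' Describes the circular-arc footprint used by the ray model: radius of
#' curvature R, the arc-center ("origin") location in in-plane image
#' coordinates (mm; x rightward/lateral, y downward/axial, origin of the
#' coordinate system at the top-left of the bitmap), and the sound speed the
#' scanner assumed when forming the image.
#'
#' @param radius_mm radius of curvature R of the footprint arc (mm).
#' @param origin_mm length-2 arc-center location (mm, image coordinates). For
#'   a probe whose arc apex touches the top of the image at lateral position
#'   x0 the origin is c(x0, -radius_mm); see [arc_origin_from_apex()].
#' @param c_cal assumed (machine) speed of sound in m/s; almost always 1540.
#' @return Object of class \code{probe_arc}.
#' @export
probe_arc_geometry <- function(radius_mm, origin_mm, c_cal = 1540) {
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1, radius_mm > 0,
            is.numeric(origin_mm), length(origin_mm) == 2,
            all(is.finite(origin_mm)),
            is.numeric(c_cal), length(c_cal) == 1, c_cal > 0)
  structure(list(radius_mm = radius_mm, origin_mm = as.numeric(origin_mm),
                 c_cal = c_cal),
            class = "probe_arc")
}

#' Arc origin for an apex-at-top footprint
#'
#' Helper placing the arc center a radius above the image top edge, with the
#' apex of the footprint at lateral position \code{apex_x_mm}, y = 0.
#'
#' @param radius_mm footprint radius of curvature (mm).
#' @param apex_x_mm lateral position of the arc apex (mm); typically the
#'   image x-center.
#' @return Length-2 origin (mm).
#' @export
arc_origin_from_apex <- function(radius_mm, apex_x_mm) {
  c(apex_x_mm, -radius_mm)
}

#' Ray parameters of an in-plane point
#'
#' Distance D_im from the arc origin to the point and the signed angle theta
#' between the origin-to-point ray and the axial (downward) direction. theta
#' is positive for points in the left half of the image (lateral coordinate
#' smaller than the arc origin's).
#'
#' @param point_mm length-2 in-plane point (mm) or n x 2 matrix of points.
#' @param geometry \code{probe_arc} object.
#' @return List with \code{d_im_mm} and \code{theta_rad} (vectors for matrix
#'   input).
#' @export
ray_params <- function(point_mm, geometry) {
  stopifnot(inherits(geometry, "probe_arc"))
  p <- if (is.matrix(point_mm)) point_mm else matrix(point_mm, ncol = 2)
  stopifnot(ncol(p) == 2)
  dx <- p[, 1] - geometry$origin_mm[1]
  dy <- p[, 2] - geometry$origin_mm[2]
  d <- sqrt(dx^2 + dy^2)
  if (any(d < geometry$radius_mm - 1e-9))
    stop("point lies inside the probe footprint arc (D_im < R)")
  theta <- atan2(-dx, dy)
  list(d_im_mm = d, theta_rad = theta)
}

#' Ray-model speed-of-sound correction of in-plane points
#'
#' Shifts each segmented point along its scan line to account for the true
#' sound speed c_a of the coupling medium differing from the machine's
#' assumed c_cal:
#' delta = (D_im - R) (1 - c_a / c_cal); delta_x = delta sin(theta);
#' delta_y = delta cos(theta); corrected point = (x + delta_x, y - delta_y).
#' When c_a = c_cal the correction is exactly the identity.
#'
#' @inheritParams ray_params
#' @param c_a actual speed of sound in the medium (m/s), e.g. from
#'   [water_sound_speed()].
#' @return Corrected point(s), same shape as the input.
#' @export
correct_point <- function(point_mm, geometry, c_a) {
  stopifnot(is.numeric(c_a), length(c_a) == 1, c_a > 0)
  rp <- ray_params(point_mm, geometry)
  delta <- (rp$d_im_mm - geometry$radius_mm) * (1 - c_a / geometry$c_cal)
  dx <- delta * sin(rp$theta_rad)
  dy <- delta * cos(rp$theta_rad)
  if (is.matrix(point_mm)) {
    cbind(point_mm[, 1] + dx, point_mm[, 2] - dy)
  } else {
    c(point_mm[1] + dx, point_mm[2] - dy)
  }
}

#' Apply speed correction to an observation table
#'
#' Converts each observation's pixel coordinates to mm, applies
#' [correct_point()], and writes the corrected positions back as pixel
#' coordinates so the table can flow into [calibrate()] unchanged.
#'
#' @param obs observation (or view) data frame.
#' @param geometry \code{probe_arc} object.
#' @param c_a actual sound speed (m/s).
#' @return The data frame with corrected \code{x_I_px}, \code{y_I_px}.
#' @export
correct_observations <- function(obs, geometry, c_a) {
  .check_columns(obs, c("x_I_px", "y_I_px", "s_x_mm_per_px", "s_y_mm_per_px"),
                 "observation table")
  pts <- cbind(obs$x_I_px * obs$s_x_mm_per_px,
               obs$y_I_px * obs$s_y_mm_per_px)
  cor <- correct_point(pts, geometry, c_a)
  obs$x_I_px <- cor[, 1] / obs$s_x_mm_per_px
  obs$y_I_px <- cor[, 2] / obs$s_y_mm_per_px
  obs
}
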