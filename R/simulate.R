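# Virtual freehand-3D-ultrasound test bench.
#
# Emulates actuator-stepped acquisition of point-target phantoms with a
# tracked curvilinear probe: phantom geometries (single cross-wire target,
# 7 collinear screw heads), stepped depth levels, full-field-of-view vs
# central-only target coverage, Gaussian segmentation noise in pixels, and
# tracker noise injected at the IR-diode level and propagated through rigid
# pose refitting. Every generated observation carries its exact ground truth,
# so the calibration solver and the evaluation metrics can be tested without
# hardware.
#
# Image coordinates: x rightward (lateral), y downward (axial/depth), origin
# at the top-left of the bitmap; in-plane points are (x, y, 0) in mm after
# pixel scaling. The probe frame has x = elevation (out of plane),
# y = lateral, z = axial.

# rotation aligning image axes with phantom axes when the probe is held
# perpendicular to a lateral target line: image x -> phantom x, image y
# (down) -> phantom -z (up), image z -> phantom y
.R_PERPENDICULAR <- matrix(c(1, 0, 0,
                             0, 0, -1,
                             0, 1, 0), 3, 3, byrow = TRUE)

#' Ground-truth description of a simulated freehand 3D ultrasound system
#'
#' Bundles everything the simulator needs to know about the (virtual)
#' hardware: the true image-to-probe calibration, the curvilinear footprint
#' geometry, the bitmap extent and pixel scales, the depth setting, and the
#' fan half-angle used for field-of-view visibility.
#'
#' The default true calibration has all six parameters away from trivial
#' values (the base alignment maps image lateral/axial onto probe
#' lateral/axial, i.e. alpha and gamma near 90 degrees, perturbed by a few
#' degrees) so that sign and axis-ordering bugs cannot cancel.
#'
#' @param true_calib \code{calib_params}; the ground-truth image-to-probe
#'   transform.
#' @param radius_mm footprint radius of curvature (mm).
#' @param image_width_px,image_height_px bitmap size in pixels.
#' @param s_x,s_y pixel scales (mm/pixel).
#' @param depth_setting imaging depth setting (mm).
#' @param fan_halfangle_rad half-angle of the curvilinear fan (radians); with
#'   the footprint radius it determines which image regions contain signal.
#' @param c_cal machine-assumed sound speed (m/s).
#' @return Object of class \code{system_truth}.
#' @export
system_truth <- function(true_calib = calib_params(pi / 2 + 0.05, -0.04,
                                                   pi / 2 + 0.06,
                                                   1.5, -48, 12),
                         radius_mm = 40,
                         image_width_px = 512, image_height_px = 480,
                         s_x = 0.2, s_y = 0.2,
                         depth_setting = 90,
                         fan_halfangle_rad = pi / 6,
                         c_cal = 1540) {
  stopifnot(inherits(true_calib, "calib_params"),
            s_x > 0, s_y > 0, depth_setting > 0,
            image_width_px > 0, image_height_px > 0,
            fan_halfangle_rad > 0, fan_halfangle_rad < pi / 2)
  width_mm <- image_width_px * s_x
  geom <- probe_arc_geometry(radius_mm,
                             arc_origin_from_apex(radius_mm, width_mm / 2),
                             c_cal)
  structure(list(true_calib = true_calib,
                 probe_geometry = geom,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px,
                 s_x = s_x, s_y = s_y,
                 width_mm = width_mm,
                 height_mm = image_height_px * s_y,
                 depth_setting = depth_setting,
                 fan_halfangle_rad = fan_halfangle_rad),
            class = "system_truth")
}

#' Is an in-plane point inside the imaged fan?
#'
#' A point is visible when it lies within the bitmap, no deeper than the
#' depth setting, below the footprint arc, and within the fan half-angle of
#' the axial direction through the arc origin.
#'
#' @param point_mm length-2 point or n x 2 matrix (mm, image coordinates).
#' @param truth \code{system_truth} object.
#' @return Logical vector.
#' @export
in_fan <- function(point_mm, truth) {
  p <- if (is.matrix(point_mm)) point_mm else matrix(point_mm, ncol = 2)
  geom <- truth$probe_geometry
  dx <- p[, 1] - geom$origin_mm[1]
  dy <- p[, 2] - geom$origin_mm[2]
  d <- sqrt(dx^2 + dy^2)
  theta <- atan2(-dx, dy)
  p[, 1] >= 0 & p[, 1] <= truth$width_mm &
    p[, 2] >= 0 & p[, 2] <= min(truth$height_mm, truth$depth_setting) &
    d >= geom$radius_mm &
    abs(theta) <= truth$fan_halfangle_rad
}

#' Point-target phantom geometries
#'
#' \code{cross_wire}: the single intersection point of two crossed wires, at
#' the phantom-frame origin. \code{collinear7}: seven screw heads spaced
#' 15 mm apart along the phantom x-axis, centred on the origin.
#'
#' @param kind "cross_wire" or "collinear7".
#' @param spacing_mm inter-screw spacing for the collinear phantom (mm).
#' @return n x 3 matrix of target coordinates in the phantom frame (mm).
#' @export
make_phantom <- function(kind = c("cross_wire", "collinear7"),
                         spacing_mm = 15) {
  kind <- match.arg(kind)
  switch(kind,
         cross_wire = matrix(c(0, 0, 0), 1, 3),
         collinear7 = cbind(seq(-3, 3) * spacing_mm, 0, 0))
}

#' Acquisition plan for actuator-stepped calibration imaging
#'
#' Describes how the probe is stepped over the phantom: the phantom kind, the
#' lateral coverage (full field of view or only the central third of the
#' lateral extent), and the actuator depth schedule (number of levels,
#' spacing, and the depth of the most superficial level in the image).
#'
#' Defaults follow the stepped single-angle protocol: 6 depth levels 10 mm
#' apart starting 35 mm below the footprint apex under a 90 mm depth setting,
#' 7 lateral placements per level for the cross-wire target.
#'
#' @param phantom_kind "cross_wire" or "collinear7".
#' @param coverage "full_fov" or "central_only".
#' @param n_depth number of depth levels.
#' @param depth_spacing_mm actuator step between levels (mm).
#' @param first_depth_mm image depth of the most superficial level (mm).
#' @param n_lateral cross-wire lateral placements per level (ignored for the
#'   collinear phantom, whose screws are fixed).
#' @return Object of class \code{acquisition_plan}.
#' @export
acquisition_plan <- function(phantom_kind = c("cross_wire", "collinear7"),
                             coverage = c("full_fov", "central_only"),
                             n_depth = 6, depth_spacing_mm = 10,
                             first_depth_mm = 35, n_lateral = 7) {
  phantom_kind <- match.arg(phantom_kind)
  coverage <- match.arg(coverage)
  stopifnot(n_depth >= 1, depth_spacing_mm > 0, first_depth_mm > 0,
            n_lateral >= 1)
  structure(list(phantom_kind = phantom_kind, coverage = coverage,
                 n_depth = n_depth, depth_spacing_mm = depth_spacing_mm,
                 first_depth_mm = first_depth_mm, n_lateral = n_lateral),
            class = "acquisition_plan")
}

# fan half-width (mm of lateral offset from the apex axis) at image depth y
.fan_halfwidth <- function(y, truth) {
  (y + truth$probe_geometry$radius_mm) * tan(truth$fan_halfangle_rad)
}

#' Expand an acquisition plan into target placements
#'
#' Lays the plan out in image coordinates: for each depth level, where each
#' point target appears in the image plane (mm), with field-of-view
#' visibility masking applied. For the cross-wire phantom each placement is a
#' separate image (the single target is re-imaged at several lateral
#' positions per level); for the collinear phantom each depth level is one
#' image showing every screw the fan can see, so the most superficial level
#' is truncated to the inner screws.
#'
#' @param plan \code{acquisition_plan}.
#' @param truth \code{system_truth}.
#' @return Data frame with columns image_id, depth_mm, target_id,
#'   image_x_mm, image_y_mm. Row count is the total number of visible point
#'   targets in the plan.
#' @export
plan_acquisition <- function(plan, truth) {
  stopifnot(inherits(plan, "acquisition_plan"), inherits(truth, "system_truth"))
  depths <- plan$first_depth_mm + (seq_len(plan$n_depth) - 1) * plan$depth_spacing_mm
  if (max(depths) > min(truth$height_mm, truth$depth_setting))
    stop("acquisition plan places targets deeper than the imaged extent")
  cx <- truth$probe_geometry$origin_mm[1]
  rows <- list()
  image_id <- 0L

  if (plan$phantom_kind == "cross_wire") {
    for (j in seq_along(depths)) {
      y <- depths[j]
      # usable lateral half-span at this depth: 95% of the fan half-width
      # (keeping targets off the exact fan edge), clipped to the bitmap.
      # Central-only coverage clusters the targets in the middle fifth of
      # the lateral extent: a band narrow relative to the full span, as in
      # protocols that image the target only near the beam axis
      span <- min(0.95 * .fan_halfwidth(y, truth),
                  0.98 * min(cx, truth$width_mm - cx))
      if (plan$coverage == "central_only")
        span <- min(span, truth$width_mm / 10)
      # the most superficial level has the smallest lateral dimension: fewer
      # placements fit across it
      n_j <- if (j == 1) max(1, plan$n_lateral - 2) else plan$n_lateral
      xs <- cx + seq(-span, span, length.out = n_j)
      for (x in xs) {
        if (!in_fan(c(x, y), truth)) next
        image_id <- image_id + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = image_id, depth_mm = y, target_id = 1L,
          image_x_mm = x, image_y_mm = y)
      }
    }
  } else {
    offsets <- make_phantom("collinear7")[, 1]
    for (j in seq_along(depths)) {
      y <- depths[j]
      xs <- cx + offsets
      vis <- in_fan(cbind(xs, y), truth)
      if (!any(vis)) next
      image_id <- image_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = image_id, depth_mm = y,
        target_id = which(vis),
        image_x_mm = xs[vis], image_y_mm = y)
    }
  }
  if (!length(rows))
    stop("acquisition plan produced no visible targets")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default probe-mounted IR-diode layout
#'
#' Five non-coplanar marker positions in the rigid-body frame, spanning
#' roughly 100 mm, similar in spirit to an optical-tracker rigid body mounted
#' on a probe or phantom.
#'
#' @return 5 x 3 matrix of diode coordinates (mm).
#' @export
default_diode_layout <- function() {
  matrix(c(0, 0, 0,
           100, 0, 0,
           0, 80, 0,
           90, 70, 30,
           40, 30, 60), ncol = 3, byrow = TRUE)
}

#' Tracked pose estimated from noisy marker positions
#'
#' Models how an optical tracker degrades a rigid-body pose: each diode's
#' true world position is perturbed with isotropic Gaussian noise and the
#' pose is refit by rigid registration of the body-frame layout onto the
#' noisy world positions. With more diodes the refit averages the individual
#' position errors, so pose error shrinks.
#'
#' @param true_pose 4x4 rigid transform (body to world).
#' @param diode_layout n x 3 body-frame marker coordinates (n >= 3,
#'   non-collinear).
#' @param sigma_mm isotropic marker position noise SD (mm); 0 returns
#'   \code{true_pose} exactly.
#' @return 4x4 rigid transform (the tracker's pose estimate). Uses the
#'   current RNG state; seed via \code{set.seed()} for reproducibility.
#' @export
pose_from_markers <- function(true_pose, diode_layout = default_diode_layout(),
                              sigma_mm = 0) {
  stopifnot(is_rigid_transform(true_pose), sigma_mm >= 0)
  if (sigma_mm == 0) return(true_pose)
  world <- apply_transform(true_pose, diode_layout)
  world <- world + matrix(stats::rnorm(length(world), sd = sigma_mm),
                          nrow(world), 3)
  fit_rigid(diode_layout, world)
}

#' Noise model for the simulator
#'
#' Defaults emulate a careful manual segmentation (0.5 mm at the default
#' 0.2 mm/px scale) and a research-grade optical tracker (0.15 mm per-marker
#' jitter). Pass zeros for an exact, noiseless simulation.
#'
#' @param seg_sigma_px segmentation noise SD in pixels (isotropic, Gaussian).
#' @param diode_sigma_mm IR-diode world-position noise SD in mm; propagated
#'   into the poses through rigid refitting.
#' @param seed RNG seed; identical seeds give bit-identical simulations.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(seg_sigma_px = 2.5, diode_sigma_mm = 0.15, seed = 1L) {
  stopifnot(seg_sigma_px >= 0, diode_sigma_mm >= 0,
            is.finite(seed))
  structure(list(seg_sigma_px = seg_sigma_px, diode_sigma_mm = diode_sigma_mm,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# default (arbitrary, non-trivial) placement of the phantom in the world
.default_world_to_phantom <- function() {
  euler_zyx_to_transform(c(0.3, -0.4, 0.2), c(120, -80, 60))
}

#' Simulate a calibration observation set
#'
#' Executes an acquisition plan on the virtual system: for every planned
#' placement the exact pixel coordinates are obtained by inverting the
#' ground-truth transform chain (so the noiseless set has zero residual at
#' the true calibration), then segmentation noise is added to the pixels and
#' tracker noise is injected at the diode level into both the probe pose and
#' the phantom pose.
#'
#' @param truth \code{system_truth}.
#' @param plan \code{acquisition_plan}.
#' @param noise \code{noise_model} (default: noiseless, seed 1).
#' @param world_to_phantom 4x4 pose of the world in the phantom frame
#'   (Ph T_W); defaults to a fixed non-trivial transform.
#' @param diode_layout marker layout used for pose refitting under tracker
#'   noise.
#' @return Observation data frame (see [calibrate()] for the schema) with
#'   attribute \code{"plan"} holding the placement table. Targets whose noisy
#'   pixel falls outside the bitmap are dropped with a warning.
#' @export
simulate_observations <- function(truth, plan, noise = noise_model(),
                                  world_to_phantom = .default_world_to_phantom(),
                                  diode_layout = default_diode_layout()) {
  stopifnot(inherits(truth, "system_truth"), inherits(noise, "noise_model"))
  placements <- plan_acquisition(plan, truth)
  set.seed(noise$seed)
  targets <- make_phantom(plan$phantom_kind)
  t_pi <- calib_transform(truth$true_calib)
  t_ip <- invert_transform(t_pi)
  t_w_ph <- invert_transform(world_to_phantom)

  rows <- vector("list", nrow(placements))
  k <- 0L
  for (img in unique(placements$image_id)) {
    pl <- placements[placements$image_id == img, , drop = FALSE]
    # image plane pose in the phantom frame: the (first) planned target of
    # this image anchors the plane; with the perpendicular alignment every
    # other target of the image lands exactly in plane
    anchor_t <- targets[pl$target_id[1], ]
    anchor_img <- c(pl$image_x_mm[1], pl$image_y_mm[1], 0)
    t_ph_i <- rigid_transform(.R_PERPENDICULAR,
                              anchor_t - .R_PERPENDICULAR %*% anchor_img)
    t_w_p_true <- t_w_ph %*% t_ph_i %*% t_ip

    # tracked poses: perturb diodes, refit
    t_w_p <- pose_from_markers(t_w_p_true, diode_layout, noise$diode_sigma_mm)
    t_w_ph_noisy <- pose_from_markers(t_w_ph, diode_layout,
                                      noise$diode_sigma_mm)
    t_ph_w <- invert_transform(t_w_ph_noisy)

    t_i_ph <- invert_transform(t_ph_i)
    for (r in seq_len(nrow(pl))) {
      p_img <- apply_transform(t_i_ph, targets[pl$target_id[r], ])
      px <- p_img[1] / truth$s_x + stats::rnorm(1, sd = noise$seg_sigma_px)
      py <- p_img[2] / truth$s_y + stats::rnorm(1, sd = noise$seg_sigma_px)
      k <- k + 1L
      rows[[k]] <- data.frame(
        target_id = sprintf("img%03d_t%d", img, pl$target_id[r]),
        x_I_px = px, y_I_px = py,
        s_x_mm_per_px = truth$s_x, s_y_mm_per_px = truth$s_y,
        rbind(stats::setNames(transform_to_row_major(t_ph_w),
                              .pose_cols("T_ph_w"))),
        rbind(stats::setNames(transform_to_row_major(t_w_p),
                              .pose_cols("T_w_p"))),
        truth_x_mm = targets[pl$target_id[r], 1],
        truth_y_mm = targets[pl$target_id[r], 2],
        truth_z_mm = targets[pl$target_id[r], 3])
    }
  }
  obs <- do.call(rbind, rows)
  inside <- obs$x_I_px >= 0 & obs$x_I_px <= truth$image_width_px &
    obs$y_I_px >= 0 & obs$y_I_px <= truth$image_height_px
  if (any(!inside)) {
    warning(sprintf("%d noisy target(s) fell outside the image extent and were excluded",
                    sum(!inside)))
    obs <- obs[inside, , drop = FALSE]
  }
  rownames(obs) <- NULL
  attr(obs, "plan") <- placements
  obs
}

#' Simulate views of a fixed pin head for the evaluation metrics
#'
#' Emulates the precision/accuracy experiments: a single pin head fixed in
#' the world is imaged repeatedly from random viewing angles and random
#' positions across the field of view. Each view records the pixel
#' coordinates and the tracked probe pose.
#'
#' @param truth \code{system_truth}.
#' @param n_views number of sightings.
#' @param pin_world length-3 world position of the pin head (mm).
#' @param noise \code{noise_model}.
#' @param max_tilt_rad half-range of the uniform random rotation about each
#'   axis applied to the probe between views (radians).
#' @param diode_layout marker layout for the tracked probe pose.
#' @return View data frame (see [reconstruct_world()]) with attribute
#'   \code{"pin_world"}.
#' @export
simulate_views <- function(truth, n_views = 50,
                           pin_world = c(150, -100, 80),
                           noise = noise_model(),
                           max_tilt_rad = pi / 6,
                           diode_layout = default_diode_layout()) {
  stopifnot(inherits(truth, "system_truth"), n_views >= 1)
  set.seed(noise$seed)
  t_ip <- invert_transform(calib_transform(truth$true_calib))
  cx <- truth$probe_geometry$origin_mm[1]
  rows <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    # random in-fan image position for the pin
    repeat {
      y <- stats::runif(1, 0.15, 0.95) * min(truth$height_mm,
                                             truth$depth_setting)
      x <- cx + stats::runif(1, -1, 1) * 0.95 * .fan_halfwidth(y, truth)
      if (in_fan(c(x, y), truth)) break
    }
    p_img <- c(x, y, 0)
    tilt <- stats::runif(3, -max_tilt_rad, max_tilt_rad)
    r_wi <- .rot_z(tilt[1]) %*% .rot_y(tilt[2]) %*% .rot_x(tilt[3]) %*%
      .R_PERPENDICULAR
    t_w_i <- rigid_transform(r_wi, pin_world - r_wi %*% p_img)
    t_w_p_true <- t_w_i %*% t_ip
    t_w_p <- pose_from_markers(t_w_p_true, diode_layout, noise$diode_sigma_mm)
    rows[[v]] <- data.frame(
      view_id = v,
      x_I_px = x / truth$s_x + stats::rnorm(1, sd = noise$seg_sigma_px),
      y_I_px = y / truth$s_y + stats::rnorm(1, sd = noise$seg_sigma_px),
      s_x_mm_per_px = truth$s_x, s_y_mm_per_px = truth$s_y,
      rbind(stats::setNames(transform_to_row_major(t_w_p),
                            .pose_cols("T_w_p"))))
  }
  views <- do.call(rbind, rows)
  rownames(views) <- NULL
  attr(views, "pin_world") <- pin_world
  views
}
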