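# Point-based probe calibration: map segmented point targets through the
# tracked transform chain, evaluate the mean residual, and solve for the six
# image-to-probe parameters by nonlinear least squares from a closed-form
# start.
#
# An observation set is a data frame with one row per segmented point target:
#   target_id                          label
#   x_I_px, y_I_px                     segmented pixel coordinates
#   s_x_mm_per_px, s_y_mm_per_px       pixel-to-mm scale factors
#   T_ph_w_00 .. T_ph_w_33             world -> phantom pose, row-major
#   T_w_p_00  .. T_w_p_33              probe -> world pose, row-major
#   truth_x_mm, truth_y_mm, truth_z_mm digitized target position, phantom frame

.pose_cols <- function(prefix) {
  idx <- expand.grid(col = 0:3, row = 0:3)
  sprintf("%s_%d%d", prefix, idx$row, idx$col)
}

OBS_COLUMNS <- c(
  "target_id", "x_I_px", "y_I_px", "s_x_mm_per_px", "s_y_mm_per_px",
  .pose_cols("T_ph_w"), .pose_cols("T_w_p"),
  "truth_x_mm", "truth_y_mm", "truth_z_mm"
)

VIEW_COLUMNS <- c(
  "view_id", "x_I_px", "y_I_px", "s_x_mm_per_px", "s_y_mm_per_px",
  .pose_cols("T_w_p")
)

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(df)
}

.extract_pose <- function(df, prefix, i, validate = TRUE) {
  transform_from_row_major(as.numeric(df[i, .pose_cols(prefix)]),
                           validate = validate)
}

# unpack an observation data frame into the pieces the solver needs:
# scaled image points (z = 0), per-row combined pose chain, and truths
.obs_unpack <- function(obs) {
  .check_columns(obs, OBS_COLUMNS, "observation table")
  n <- nrow(obs)
  if (n < 1) stop("observation table is empty")
  if (any(obs$s_x_mm_per_px <= 0) || any(obs$s_y_mm_per_px <= 0))
    stop("scale factors must be positive")
  if (any(!is.finite(obs$x_I_px)) || any(!is.finite(obs$y_I_px)) ||
      any(obs$x_I_px < 0) || any(obs$y_I_px < 0))
    stop("pixel coordinates must be finite and non-negative")
  img <- cbind(obs$x_I_px * obs$s_x_mm_per_px,
               obs$y_I_px * obs$s_y_mm_per_px,
               0)
  chain <- vector("list", n)
  for (i in seq_len(n)) {
    t_ph_w <- .extract_pose(obs, "T_ph_w", i)
    t_w_p <- .extract_pose(obs, "T_w_p", i)
    chain[[i]] <- t_ph_w %*% t_w_p
  }
  truth <- cbind(obs$truth_x_mm, obs$truth_y_mm, obs$truth_z_mm)
  list(img = img, chain = chain, truth = truth, n = n)
}

#' Calibration parameters (the six unknowns)
#'
#' Bundles the z-y-x Euler angles (alpha about the axial z axis, beta about
#' the lateral y axis, gamma about the elevation x axis, radians) and the
#' translation of the image origin along the probe's elevation/lateral/axial
#' axes (mm). Together they define the image-to-probe transform.
#'
#' @param alpha,beta,gamma Euler angles in radians (z-y-x sequence).
#' @param x,y,z translation components in mm.
#' @return Object of class \code{calib_params}.
#' @seealso [calib_transform()], [calib_params_from_transform()]
#' @export
calib_params <- function(alpha = 0, beta = 0, gamma = 0,
                         x = 0, y = 0, z = 0) {
  v <- c(alpha, beta, gamma, x, y, z)
  if (length(v) != 6 || !all(is.finite(v)))
    stop("calibration parameters must be six finite values")
  out <- list(angles = normalize_angle(v[1:3]), translation = v[4:6])
  class(out) <- "calib_params"
  out
}

#' @export
print.calib_params <- function(x, ...) {
  cat("Image-to-probe calibration parameters\n")
  cat(sprintf("  alpha (axial z):     %10.4f deg\n", x$angles[1] * 180 / pi))
  cat(sprintf("  beta  (lateral y):   %10.4f deg\n", x$angles[2] * 180 / pi))
  cat(sprintf("  gamma (elevation x): %10.4f deg\n", x$angles[3] * 180 / pi))
  cat(sprintf("  x (elevation):       %10.4f mm\n", x$translation[1]))
  cat(sprintf("  y (lateral):         %10.4f mm\n", x$translation[2]))
  cat(sprintf("  z (axial):           %10.4f mm\n", x$translation[3]))
  invisible(x)
}

#' Image-to-probe transform for a parameter set
#'
#' @param params \code{calib_params} object.
#' @return 4x4 rigid transform (image frame to probe frame).
#' @export
calib_transform <- function(params) {
  stopifnot(inherits(params, "calib_params"))
  euler_zyx_to_transform(params$angles, params$translation)
}

#' Recover calibration parameters from an image-to-probe transform
#'
#' @param m 4x4 rigid transform.
#' @return \code{calib_params} object.
#' @export
calib_params_from_transform <- function(m) {
  e <- transform_to_euler_zyx(m)
  calib_params(e$angles[1], e$angles[2], e$angles[3],
               e$translation[1], e$translation[2], e$translation[3])
}

.params_vec <- function(params) c(params$angles, params$translation)
.params_from_vec <- function(v) calib_params(v[1], v[2], v[3], v[4], v[5], v[6])

#' Map segmented image points to the phantom frame
#'
#' Evaluates the tracked transform chain for each observation: the scaled
#' pixel point (s_x x_I, s_y y_I, 0) is carried image -> probe -> world ->
#' phantom using the candidate calibration and the two tracked poses stored
#' with the observation.
#'
#' @param obs observation data frame (see [simulate_observations()] or
#'   [read_observations()] for the schema).
#' @param params \code{calib_params} candidate calibration.
#' @return n x 3 matrix of mapped phantom-frame coordinates (mm).
#' @export
map_image_to_phantom <- function(obs, params) {
  u <- .obs_unpack(obs)
  t_pi <- calib_transform(params)
  out <- matrix(NA_real_, u$n, 3)
  for (i in seq_len(u$n)) {
    m <- u$chain[[i]] %*% t_pi
    out[i, ] <- m[1:3, 1:3] %*% u$img[i, ] + m[1:3, 4]
  }
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}

#' Mean calibration residual D
#'
#' The residual of a candidate calibration over an observation set: the mean
#' Euclidean distance (mm) between each target's digitized phantom-frame
#' position and its position mapped from the image through the tracked chain.
#'
#' @inheritParams map_image_to_phantom
#' @return Mean residual distance in mm (non-negative scalar).
#' @export
residual_error <- function(obs, params) {
  if (nrow(obs) < 1) stop("at least one observation is required")
  mapped <- map_image_to_phantom(obs, params)
  truth <- cbind(obs$truth_x_mm, obs$truth_y_mm, obs$truth_z_mm)
  mean(sqrt(rowSums((truth - mapped)^2)))
}

#' Closed-form calibration initializer
#'
#' Pulls each target's digitized position back into the probe frame through
#' the inverted tracked poses, then registers the scaled image points (which
#' lie in the z = 0 plane) onto those probe-frame points with [fit_rigid()].
#' With noiseless data this already is the exact calibration; with noise it
#' provides the starting point for [calibrate()].
#'
#' @inheritParams map_image_to_phantom
#' @return \code{calib_params} object.
#' @export
closed_form_init <- function(obs) {
  u <- .obs_unpack(obs)
  if (u$n < 3)
    stop("degenerate configuration: at least 3 observations are required")
  dst <- matrix(NA_real_, u$n, 3)
  for (i in seq_len(u$n)) {
    inv_chain <- invert_transform(u$chain[[i]])
    dst[i, ] <- apply_transform(inv_chain, u$truth[i, ])
  }
  calib_params_from_transform(fit_rigid(u$img, dst))
}

#' Solve the point-based probe calibration
#'
#' Estimates the six image-to-probe parameters by Levenberg-Marquardt least
#' squares on the stacked 3n-vector of phantom-frame residuals
#' (truth - mapped), started from the closed-form initializer. Minimizing
#' the stacked residual vector has the same minimizer as the mean-distance
#' residual D in the noiseless limit but a smoother objective.
#'
#' @param obs observation data frame with at least 3 non-degenerate rows.
#' @param init optional \code{calib_params} starting point; defaults to
#'   [closed_form_init()] so the fit is deterministic.
#' @param max_iter iteration cap for the optimizer.
#' @param ptol relative parameter-step convergence tolerance.
#' @return Object of class \code{calibration}: \code{params},
#'   \code{transform}, \code{residual_mm} (mean distance D), \code{n_targets},
#'   \code{converged}, \code{iterations}, \code{message}.
#' @examples
#' truth <- system_truth()
#' plan <- acquisition_plan("cross_wire")
#' obs <- simulate_observations(truth, plan)
#' fit <- calibrate(obs)
#' fit$residual_mm
#' @export
calibrate <- function(obs, init = NULL, max_iter = 200, ptol = 1e-10) {
  u <- .obs_unpack(obs)
  if (u$n < 3)
    stop("degenerate configuration: at least 3 observations are required")
  if (is.null(init)) init <- closed_form_init(obs)
  stopifnot(inherits(init, "calib_params"))

  resid_fn <- function(theta) {
    t_pi <- euler_zyx_to_transform(theta[1:3], theta[4:6])
    r <- matrix(NA_real_, u$n, 3)
    for (i in seq_len(u$n)) {
      m <- u$chain[[i]] %*% t_pi
      r[i, ] <- u$truth[i, ] - (m[1:3, 1:3] %*% u$img[i, ] + m[1:3, 4])
    }
    as.numeric(r)
  }

  fit <- minpack.lm::nls.lm(
    par = .params_vec(init), fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ptol = ptol, ftol = 1e-12, gtol = 0))

  params <- .params_from_vec(fit$par)
  # keep whichever of {refined, initial} has the smaller mean residual; LM
  # guarantees non-increase of the sum of squares, not of the mean distance
  d_init <- residual_error(obs, init)
  d_fit <- residual_error(obs, params)
  if (d_init < d_fit) {
    params <- init
    d_fit <- d_init
  }
  out <- list(
    params = params,
    transform = calib_transform(params),
    residual_mm = d_fit,
    n_targets = u$n,
    converged = fit$info %in% 1:4,
    iterations = fit$niter,
    message = fit$message
  )
  class(out) <- "calibration"
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Probe calibration from %d point targets\n", x$n_targets))
  print(x$params)
  cat(sprintf("  mean residual D: %.6f mm\n", x$residual_mm))
  cat(sprintf("  converged: %s (%d iterations)\n",
              ifelse(x$converged, "yes", "no"), x$iterations))
  invisible(x)
}
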