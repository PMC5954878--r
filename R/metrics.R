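# Calibration quality metrics: calibration reproducibility, point
# reconstruction precision, point reconstruction accuracy, and distance
# reconstruction accuracy. Each pools its observations combinatorially and
# returns a metric_summary (mean / SD / max / min / pool size).
#
# A "view" table holds repeated sightings of a fixed physical pin head:
# columns view_id, x_I_px, y_I_px, s_x_mm_per_px, s_y_mm_per_px and the
# probe -> world pose T_w_p_00..T_w_p_33 (row-major).

.metric_summary <- function(values) {
  values <- as.numeric(values)
  out <- list(mean = mean(values),
              sd = stats::sd(values),
              max = max(values),
              min = min(values),
              n_pooled = length(values))
  class(out) <- "metric_summary"
  out
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("mean %.4f (SD %.4f), max %.4f, min %.4f, n = %d\n",
              x$mean, x$sd, x$max, x$min, x$n_pooled))
  invisible(x)
}

#' Convert metric summaries to a data frame
#'
#' @param summaries named list of \code{metric_summary} objects.
#' @return Data frame with columns metric, mean, sd, max, min, n_pooled.
#' @export
metrics_to_data_frame <- function(summaries) {
  stopifnot(is.list(summaries), length(names(summaries)) == length(summaries))
  do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(metric = nm, mean = s$mean, sd = s$sd, max = s$max,
               min = s$min, n_pooled = s$n_pooled)
  }))
}

.views_unpack <- function(views) {
  .check_columns(views, VIEW_COLUMNS, "view table")
  n <- nrow(views)
  img <- cbind(views$x_I_px * views$s_x_mm_per_px,
               views$y_I_px * views$s_y_mm_per_px,
               0)
  poses <- lapply(seq_len(n), function(i) .extract_pose(views, "T_w_p", i))
  list(img = img, poses = poses, n = n)
}

#' Reconstruct world coordinates from views
#'
#' Carries each view's scaled pixel point through image -> probe -> world:
#' v_W = (W T_P) (P T_I) v_I.
#'
#' @param views view data frame.
#' @param params \code{calib_params} calibration to use.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
reconstruct_world <- function(views, params) {
  u <- .views_unpack(views)
  t_pi <- calib_transform(params)
  out <- matrix(NA_real_, u$n, 3)
  for (i in seq_len(u$n)) {
    m <- u$poses[[i]] %*% t_pi
    out[i, ] <- m[1:3, 1:3] %*% u$img[i, ] + m[1:3, 4]
  }
  colnames(out) <- c("x_mm", "y_mm", "z_mm")
  out
}

.as_params_list <- function(calibs) {
  if (inherits(calibs, "calib_params")) calibs <- list(calibs)
  calibs <- lapply(calibs, function(cc) {
    if (inherits(cc, "calibration")) cc$params else cc
  })
  if (!all(vapply(calibs, inherits, logical(1), "calib_params")))
    stop("'calibs' must be calib_params or calibration objects")
  calibs
}

#' Calibration reproducibility
#'
#' Transforms five fixed evaluation points of the image (the four corners and
#' the center of the rectangular image extent) into probe space with every
#' calibration in the set, and pools the Euclidean distances between all
#' unordered pairs of calibrations at each point. With k calibrations the
#' pool holds choose(k, 2) * 5 distances.
#'
#' @param calibs list of \code{calib_params} (or \code{calibration}) objects,
#'   length >= 2.
#' @param width_mm,height_mm image extent in mm (columns * s_x, rows * s_y).
#' @return \code{metric_summary} of the pooled distances (mm).
#' @export
calibration_reproducibility <- function(calibs, width_mm, height_mm) {
  calibs <- .as_params_list(calibs)
  k <- length(calibs)
  if (k < 2) stop("at least 2 calibrations are required")
  stopifnot(width_mm > 0, height_mm > 0)
  pts <- rbind(c(0, 0, 0), c(width_mm, 0, 0), c(0, height_mm, 0),
               c(width_mm, height_mm, 0), c(width_mm / 2, height_mm / 2, 0))
  probe_pts <- lapply(calibs, function(p) apply_transform(calib_transform(p), pts))
  pairs <- utils::combn(k, 2)
  d <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    diff <- probe_pts[[pairs[1, j]]] - probe_pts[[pairs[2, j]]]
    d <- c(d, sqrt(rowSums(diff^2)))
  }
  .metric_summary(d)
}

#' Point reconstruction precision
#'
#' Reconstructs every view of a fixed pin head into world space with each
#' calibration, pools the Euclidean distances between all unordered pairs of
#' views within a calibration, then pools across calibrations: with v views
#' and k calibrations the pool holds choose(v, 2) * k distances.
#'
#' @param views view data frame (>= 2 rows), all sightings of one pin head.
#' @param calibs list of calibrations (>= 1).
#' @return \code{metric_summary} of the pooled pairwise distances (mm).
#' @export
point_reconstruction_precision <- function(views, calibs) {
  calibs <- .as_params_list(calibs)
  if (nrow(views) < 2) stop("at least 2 views are required")
  d <- unlist(lapply(calibs, function(p) {
    as.numeric(stats::dist(reconstruct_world(views, p)))
  }))
  .metric_summary(d)
}

#' Point reconstruction accuracy
#'
#' Pools the Euclidean distance between each reconstructed pin-head position
#' and its digitized true world position over every view x calibration
#' combination (v * k distances).
#'
#' @param views view data frame (>= 1 row).
#' @param calibs list of calibrations (>= 1).
#' @param truth_world length-3 true world position of the pin head (mm).
#' @return \code{metric_summary} of the pooled errors (mm).
#' @export
point_reconstruction_accuracy <- function(views, calibs, truth_world) {
  calibs <- .as_params_list(calibs)
  if (nrow(views) < 1) stop("at least 1 view is required")
  stopifnot(length(truth_world) == 3, all(is.finite(truth_world)))
  d <- unlist(lapply(calibs, function(p) {
    rec <- reconstruct_world(views, p)
    sqrt(rowSums(sweep(rec, 2, truth_world)^2))
  }))
  .metric_summary(d)
}

#' Distance reconstruction accuracy
#'
#' For a two-pin phantom with known inter-pin distance: reconstructs every
#' view of each pin, forms the imaged distance for every (view of pin A,
#' view of pin B, calibration) triple, and pools the signed differences
#' true - imaged (v_a * v_b * k values; negative values mean the imaged
#' distance overestimated the truth).
#'
#' @param views_a,views_b view data frames for the two pins (>= 1 row each).
#' @param calibs list of calibrations (>= 1).
#' @param true_distance digitized true 3D distance between the pins (mm), > 0.
#' @return \code{metric_summary} of the pooled signed differences (mm).
#' @export
distance_reconstruction_accuracy <- function(views_a, views_b, calibs,
                                             true_distance) {
  calibs <- .as_params_list(calibs)
  if (nrow(views_a) < 1 || nrow(views_b) < 1)
    stop("at least 1 view of each point is required")
  if (!is.finite(true_distance) || true_distance <= 0)
    stop("'true_distance' must be a positive distance in mm")
  d <- unlist(lapply(calibs, function(p) {
    ra <- reconstruct_world(views_a, p)
    rb <- reconstruct_world(views_b, p)
    # all cross pairs: |ra_i - rb_j|
    cross <- sqrt(pmax(outer(rowSums(ra^2), rowSums(rb^2), "+") -
                         2 * tcrossprod(ra, rb), 0))
    true_distance - as.numeric(cross)
  }))
  .metric_summary(d)
}
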