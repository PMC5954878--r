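# Readers and writers for observation/view tables (CSV), calibration results
# (JSON, angles in degrees) and metric summaries (CSV/JSON).

#' Write an observation table to CSV
#'
#' @param obs observation data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_observations <- function(obs, path) {
  .check_columns(obs, OBS_COLUMNS, "observation table")
  utils::write.csv(obs[, OBS_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read an observation table from CSV
#'
#' Validates the schema and every stored pose; malformed rows are reported
#' with their row number.
#'
#' @param path CSV file path.
#' @return Observation data frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, check.names = FALSE)
  .check_columns(obs, OBS_COLUMNS, sprintf("'%s'", path))
  .validate_pose_rows(obs, path, c("T_ph_w", "T_w_p"))
  obs
}

#' Write a view table to CSV
#'
#' @param views view data frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_views <- function(views, path) {
  .check_columns(views, VIEW_COLUMNS, "view table")
  utils::write.csv(views[, VIEW_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a view table from CSV
#'
#' @param path CSV file path.
#' @return View data frame.
#' @export
read_views <- function(path) {
  views <- utils::read.csv(path, check.names = FALSE)
  .check_columns(views, VIEW_COLUMNS, sprintf("'%s'", path))
  .validate_pose_rows(views, path, "T_w_p")
  views
}

.validate_pose_rows <- function(df, path, prefixes) {
  for (i in seq_len(nrow(df))) {
    for (pf in prefixes) {
      ok <- tryCatch({
        .extract_pose(df, pf, i)
        TRUE
      }, error = function(e) e)
      if (!isTRUE(ok))
        stop(sprintf("'%s', row %d, pose %s: %s",
                     path, i, pf, conditionMessage(ok)))
    }
  }
  invisible(df)
}

#' Write a calibration result to JSON
#'
#' Angles are serialized in degrees, translations in mm, and the full 4x4
#' image-to-probe matrix is included row-major as an unambiguous fallback.
#'
#' @param result \code{calibration} object (or bare \code{calib_params}).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_calibration <- function(result, path) {
  if (inherits(result, "calib_params"))
    result <- list(params = result, transform = calib_transform(result),
                   residual_mm = NA_real_, n_targets = NA_integer_,
                   converged = NA, iterations = NA_integer_)
  p <- result$params
  out <- list(
    alpha_deg = p$angles[1] * 180 / pi,
    beta_deg = p$angles[2] * 180 / pi,
    gamma_deg = p$angles[3] * 180 / pi,
    x_mm = p$translation[1],
    y_mm = p$translation[2],
    z_mm = p$translation[3],
    matrix_row_major = transform_to_row_major(result$transform),
    residual_mm = result$residual_mm,
    n_targets = result$n_targets,
    converged = result$converged,
    iterations = result$iterations
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read calibration parameters from JSON
#'
#' @param path JSON file written by [write_calibration()].
#' @return \code{calib_params} object.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("alpha_deg", "beta_deg", "gamma_deg", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(need, names(j))
  if (length(missing))
    stop(sprintf("'%s' is missing field(s): %s", path,
                 paste(missing, collapse = ", ")))
  calib_params(j$alpha_deg * pi / 180, j$beta_deg * pi / 180,
               j$gamma_deg * pi / 180, j$x_mm, j$y_mm, j$z_mm)
}

#' Write metric summaries to CSV
#'
#' @param summaries named list of \code{metric_summary} objects.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(summaries, path) {
  utils::write.csv(metrics_to_data_frame(summaries), path, row.names = FALSE)
  invisible(path)
}
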