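# Shared fixture builders: hand-assembled observation/view rows and an
# independent sequential-apply oracle for the transform chain.

pose_cols <- function(prefix) {
  idx <- expand.grid(col = 0:3, row = 0:3)
  sprintf("%s_%d%d", prefix, idx$row, idx$col)
}

obs_row <- function(px, py, t_ph_w = diag(4), t_w_p = diag(4),
                    truth = c(0, 0, 0), sx = 0.1, sy = 0.1, id = "t1") {
  df <- data.frame(target_id = id, x_I_px = px, y_I_px = py,
                   s_x_mm_per_px = sx, s_y_mm_per_px = sy)
  df[pose_cols("T_ph_w")] <- as.list(as.numeric(t(t_ph_w)))
  df[pose_cols("T_w_p")] <- as.list(as.numeric(t(t_w_p)))
  df$truth_x_mm <- truth[1]; df$truth_y_mm <- truth[2]; df$truth_z_mm <- truth[3]
  df
}

view_row <- function(px, py, t_w_p = diag(4), sx = 0.1, sy = 0.1, id = 1) {
  df <- data.frame(view_id = id, x_I_px = px, y_I_px = py,
                   s_x_mm_per_px = sx, s_y_mm_per_px = sy)
  df[pose_cols("T_w_p")] <- as.list(as.numeric(t(t_w_p)))
  df
}

# oracle: map one observation row step by step with apply_transform
chain_oracle <- function(row, params) {
  p_img <- c(row$x_I_px * row$s_x_mm_per_px, row$y_I_px * row$s_y_mm_per_px, 0)
  t_pi <- calib_transform(params)
  t_w_p <- transform_from_row_major(as.numeric(row[pose_cols("T_w_p")]))
  t_ph_w <- transform_from_row_major(as.numeric(row[pose_cols("T_ph_w")]))
  apply_transform(t_ph_w, apply_transform(t_w_p, apply_transform(t_pi, p_img)))
}

random_rigid <- function() {
  euler_zyx_to_transform(stats::runif(3, -pi / 2, pi / 2),
                         stats::runif(3, -100, 100))
}

noiseless <- function(seed = 1L) noise_model(0, 0, seed)
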