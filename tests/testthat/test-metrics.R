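# The four evaluation metrics and their combinatorial pool sizes.

test_that("reconstruct_world reduces to scaling plus pose and matches the oracle", {
  zero <- calib_params()
  v0 <- view_row(0, 0)
  expect_equal(as.numeric(reconstruct_world(v0, zero)), c(0, 0, 0))

  vt <- view_row(10, 20, t_w_p = rigid_transform(diag(3), c(5, 6, 7)))
  expect_equal(as.numeric(reconstruct_world(vt, zero)), c(6, 8, 7))

  set.seed(17)
  for (i in 1:8) {
    pose <- random_rigid()
    params <- calib_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1),
                           runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20))
    v <- view_row(runif(1, 0, 500), runif(1, 0, 400), t_w_p = pose)
    p_img <- c(v$x_I_px * 0.1, v$y_I_px * 0.1, 0)
    oracle <- apply_transform(pose, apply_transform(calib_transform(params), p_img))
    expect_equal(as.numeric(reconstruct_world(v, params)), oracle,
                 tolerance = 1e-10)
  }
})

test_that("calibration reproducibility pools 5 points over all calibration pairs", {
  same <- replicate(10, calib_params(0.1, 0.2, 0.3, 1, 2, 3),
                    simplify = FALSE)
  m <- calibration_reproducibility(same, 100, 80)
  expect_equal(m$n_pooled, 225) # choose(10, 2) * 5
  expect_equal(m$mean, 0)
  expect_equal(m$max, 0)

  # two calibrations differing by a pure translation: every distance = ||t||
  a <- calib_params(0.1, -0.2, 0.4, 0, 0, 0)
  b <- calib_params(0.1, -0.2, 0.4, 3, -4, 12)
  m2 <- calibration_reproducibility(list(a, b), 100, 80)
  expect_equal(m2$n_pooled, 5)
  expect_equal(m2$mean, 13)
  expect_equal(m2$sd, 0)

  distinct <- lapply(1:10, function(i) calib_params(0.01 * i, 0, 0, i, 0, 0))
  expect_equal(calibration_reproducibility(distinct, 100, 80)$n_pooled,
               45 * 5)
  expect_error(calibration_reproducibility(list(a), 100, 80), "2 calibrations")
})

test_that("point reconstruction precision pools view pairs across calibrations", {
  truth <- system_truth()
  views <- simulate_views(truth, n_views = 50, noise = noiseless())
  calibs <- replicate(10, truth$true_calib, simplify = FALSE)
  m <- point_reconstruction_precision(views, calibs)
  expect_equal(m$n_pooled, 12250) # choose(50, 2) * 10
  expect_lt(m$max, 1e-9)          # noiseless: all views coincide

  m1 <- point_reconstruction_precision(views, list(truth$true_calib))
  expect_equal(m1$n_pooled, 1225)
  expect_error(point_reconstruction_precision(views[1, ], calibs), "2 views")
})

test_that("point reconstruction accuracy pools all view x calibration errors", {
  truth <- system_truth()
  views <- simulate_views(truth, n_views = 50, noise = noiseless())
  pin <- attr(views, "pin_world")
  calibs <- replicate(10, truth$true_calib, simplify = FALSE)
  m <- point_reconstruction_accuracy(views, calibs, pin)
  expect_equal(m$n_pooled, 500) # 50 views x 10 calibrations
  expect_lt(m$max, 1e-9)

  # identity pose, calibration offset by 1 mm in a fixed direction:
  # reconstructed = scaled pixel + (1, 0, 0); truth = scaled pixel
  v1 <- view_row(10, 20)
  off <- calib_params(0, 0, 0, 1, 0, 0)
  m2 <- point_reconstruction_accuracy(v1, list(off), c(1, 2, 0))
  expect_equal(m2$mean, 1)
})

test_that("distance reconstruction accuracy pools signed differences over triples", {
  truth <- system_truth()
  va <- simulate_views(truth, n_views = 50, pin_world = c(150, -100, 80),
                       noise = noiseless(1))
  vb <- simulate_views(truth, n_views = 50, pin_world = c(180, -60, 95),
                       noise = noiseless(2))
  true_d <- sqrt(sum((c(150, -100, 80) - c(180, -60, 95))^2))
  calibs <- replicate(10, truth$true_calib, simplify = FALSE)
  m <- distance_reconstruction_accuracy(va, vb, calibs, true_d)
  expect_equal(m$n_pooled, 25000) # 50 x 50 x 10
  expect_lt(max(abs(c(m$mean, m$max, m$min))), 1e-9)

  m1 <- distance_reconstruction_accuracy(va, vb, list(truth$true_calib), true_d)
  expect_equal(m1$n_pooled, 2500) # per-calibration image pairs

  # sign convention: imaged distance larger than truth gives negative values
  a1 <- view_row(0, 0, id = 1)
  b1 <- view_row(0, 100, id = 1) # imaged distance 10 mm
  m2 <- distance_reconstruction_accuracy(a1, b1, list(calib_params()), 8)
  expect_equal(m2$mean, -2)
  expect_error(
    distance_reconstruction_accuracy(a1, b1, list(calib_params()), -1),
    "positive")
})

test_that("all four metrics are invariant to a common rigid world-frame change", {
  truth <- system_truth()
  views <- simulate_views(truth, n_views = 12,
                          noise = noise_model(1.5, 0.1, seed = 6))
  pin <- attr(views, "pin_world")
  vb <- simulate_views(truth, n_views = 10, pin_world = pin + c(20, 5, -10),
                       noise = noise_model(1.5, 0.1, seed = 7))
  calibs <- lapply(1:3, function(i)
    calib_params(0.1 * i, -0.05 * i, 0.2, i, -i, 2 * i))
  g <- euler_zyx_to_transform(c(1.1, -0.4, 0.6), c(55, -20, 35))

  move_views <- function(v) {
    for (i in seq_len(nrow(v))) {
      tw <- transform_from_row_major(as.numeric(v[i, pose_cols("T_w_p")]))
      v[i, pose_cols("T_w_p")] <- as.list(transform_to_row_major(g %*% tw))
    }
    v
  }
  d <- sqrt(sum((pin - (pin + c(20, 5, -10)))^2))

  m_prec <- point_reconstruction_precision(views, calibs)
  m_prec_g <- point_reconstruction_precision(move_views(views), calibs)
  expect_equal(m_prec_g$mean, m_prec$mean, tolerance = 1e-9)

  m_acc <- point_reconstruction_accuracy(views, calibs, pin)
  m_acc_g <- point_reconstruction_accuracy(move_views(views), calibs,
                                           apply_transform(g, pin))
  expect_equal(m_acc_g$mean, m_acc$mean, tolerance = 1e-9)

  m_dist <- distance_reconstruction_accuracy(views, vb, calibs, d)
  m_dist_g <- distance_reconstruction_accuracy(move_views(views),
                                               move_views(vb), calibs, d)
  expect_equal(m_dist_g$mean, m_dist$mean, tolerance = 1e-9)

  # reproducibility involves no world poses at all: trivially invariant,
  # and zero iff the calibrations agree on the evaluation points
  expect_equal(calibration_reproducibility(calibs, 100, 80)$min > 0, TRUE)
})

test_that("metric summaries convert to a tidy data frame", {
  calibs <- list(calib_params(), calib_params(0, 0, 0, 1, 0, 0))
  s <- list(repro = calibration_reproducibility(calibs, 100, 80))
  df <- metrics_to_data_frame(s)
  expect_equal(df$metric, "repro")
  expect_equal(df$n_pooled, 5)
  expect_true(df$min <= df$mean && df$mean <= df$max)
})
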