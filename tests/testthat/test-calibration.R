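# The calibration core: chain mapping, mean residual D, closed-form
# initialization, and the nonlinear solve.

test_that("map_image_to_phantom reduces to pure scaling with identity chain", {
  obs <- obs_row(10, 20)
  zero <- calib_params()
  expect_equal(as.numeric(map_image_to_phantom(obs, zero)), c(1, 2, 0))

  obs5 <- obs_row(10, 20, t_ph_w = rigid_transform(diag(3), c(0, 0, 5)))
  expect_equal(as.numeric(map_image_to_phantom(obs5, zero)), c(1, 2, 5))
})

test_that("map_image_to_phantom equals the sequential apply oracle", {
  set.seed(21)
  for (i in 1:10) {
    params <- calib_params(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1),
                           runif(1, -30, 30), runif(1, -30, 30), runif(1, -30, 30))
    row <- obs_row(runif(1, 0, 500), runif(1, 0, 400),
                   t_ph_w = random_rigid(), t_w_p = random_rigid())
    expect_equal(as.numeric(map_image_to_phantom(row, params)),
                 chain_oracle(row, params), tolerance = 1e-10)
  }
})

test_that("observation validation rejects broken tables", {
  obs <- obs_row(10, 20)
  expect_error(map_image_to_phantom(obs[, -2], calib_params()), "x_I_px")
  bad <- obs; bad$s_x_mm_per_px <- -1
  expect_error(map_image_to_phantom(bad, calib_params()), "positive")
  neg <- obs; neg$x_I_px <- -5
  expect_error(map_image_to_phantom(neg, calib_params()), "non-negative")
})

test_that("residual_error is the mean of Euclidean distances", {
  zero <- calib_params()
  # mapped point (1, 2, 0); truth offset exactly 1 mm
  one <- obs_row(10, 20, truth = c(1, 2, 1))
  expect_equal(residual_error(one, zero), 1)

  three <- rbind(obs_row(10, 20, truth = c(1, 2, 1)),
                 obs_row(10, 20, truth = c(1, 2, 2)),
                 obs_row(10, 20, truth = c(1, 2, 3)))
  expect_equal(residual_error(three, zero), 2)

  expect_error(residual_error(one[0, ], zero), "observation")
})

test_that("residual is zero at the true calibration on noiseless data", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noiseless())
  expect_lt(residual_error(obs, truth$true_calib), 1e-9)
})

test_that("closed_form_init recovers the truth from noiseless data", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noiseless())
  init <- closed_form_init(obs)
  expect_equal(init$angles, truth$true_calib$angles, tolerance = 1e-6)
  expect_equal(init$translation, truth$true_calib$translation,
               tolerance = 1e-6)
})

test_that("closed_form_init rejects collinear image points", {
  pose <- random_rigid()
  obs <- do.call(rbind, lapply(1:5, function(i)
    obs_row(10 * i, 20 * i, t_w_p = pose, truth = c(i, i, 0), id = i)))
  expect_error(closed_form_init(obs), "collinear")
  expect_error(closed_form_init(obs[1:2, ]), "3 observations")
})

test_that("initialization residual is within 2x of the refined optimum under noise", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noise_model(2.5, 0, seed = 4))
  d_init <- residual_error(obs, closed_form_init(obs))
  d_opt <- calibrate(obs)$residual_mm
  expect_lte(d_opt, d_init)
  expect_lte(d_init, 2 * d_opt)
})

test_that("calibrate recovers the ground truth from noiseless data", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noiseless())
  fit <- calibrate(obs)
  expect_true(fit$converged)
  expect_equal(fit$n_targets, 40)
  expect_lt(fit$residual_mm, 1e-6)
  expect_equal(fit$params$angles, truth$true_calib$angles, tolerance = 1e-6)
  expect_equal(fit$params$translation, truth$true_calib$translation,
               tolerance = 1e-3)
})

test_that("calibrate reaches the same optimum from a perturbed start", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noise_model(2.5, 0.15, seed = 8))
  base <- calibrate(obs)
  p <- base$params
  bumped <- calib_params(p$angles[1] + 5 * pi / 180, p$angles[2] - 5 * pi / 180,
                         p$angles[3] + 5 * pi / 180,
                         p$translation[1] + 5, p$translation[2] - 5,
                         p$translation[3] + 5)
  refit <- calibrate(obs, init = bumped)
  expect_equal(refit$params$angles, base$params$angles, tolerance = 1e-6)
  expect_equal(refit$params$translation, base$params$translation,
               tolerance = 1e-4)
})

test_that("calibrate errors on degenerate input and keeps determinism", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noise_model(2.5, 0.15, seed = 2))
  expect_error(calibrate(obs[1:2, ]), "3 observations")
  a <- calibrate(obs); b <- calibrate(obs)
  expect_identical(a$params, b$params)
})

test_that("the optimum beats a coarse parameter grid around it", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noise_model(2.5, 0.15, seed = 5))
  fit <- calibrate(obs)
  d0 <- residual_error(obs, fit$params)
  v0 <- c(fit$params$angles, fit$params$translation)
  set.seed(99)
  for (i in 1:40) {
    v <- v0 + c(runif(3, -0.02, 0.02), runif(3, -2, 2))
    expect_gte(residual_error(obs, calib_params(v[1], v[2], v[3],
                                                v[4], v[5], v[6])), d0)
  }
})

test_that("recovered calibration is equivariant to a rigid phantom-frame change", {
  truth <- system_truth()
  obs <- simulate_observations(truth, acquisition_plan("cross_wire"),
                               noiseless())
  g <- euler_zyx_to_transform(c(0.2, -0.5, 0.8), c(30, -40, 25))
  moved <- obs
  for (i in seq_len(nrow(obs))) {
    t_ph_w <- transform_from_row_major(as.numeric(obs[i, pose_cols("T_ph_w")]))
    moved[i, pose_cols("T_ph_w")] <- as.list(transform_to_row_major(g %*% t_ph_w))
    moved[i, c("truth_x_mm", "truth_y_mm", "truth_z_mm")] <-
      as.list(apply_transform(g, as.numeric(
        obs[i, c("truth_x_mm", "truth_y_mm", "truth_z_mm")])))
  }
  f0 <- calibrate(obs); f1 <- calibrate(moved)
  expect_equal(f1$transform, f0$transform, tolerance = 1e-9)
})

test_that("translation recovery degrades monotonically with segmentation noise", {
  truth <- system_truth()
  plan <- acquisition_plan("cross_wire")
  sigmas_mm <- c(0, 0.25, 0.5, 1.0)
  rmse <- sapply(sigmas_mm, function(sg) {
    errs <- sapply(1:20, function(s) {
      obs <- suppressWarnings(simulate_observations(
        truth, plan, noise_model(sg / truth$s_x, 0, seed = s)))
      fit <- calibrate(obs)
      sqrt(sum((fit$params$translation - truth$true_calib$translation)^2))
    })
    sqrt(mean(errs^2))
  })
  expect_true(all(diff(rmse) >= 0))
})
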