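test_that("built-in landmark schemes match the conventional labels", {
  expect_identical(landmark_schemes("first_metatarsal"), c("TL", "TM", "TB"))
  expect_identical(landmark_schemes("calcaneus"), c("PT", "ST", "CA"))
  expect_identical(landmark_schemes("midfoot"), c("VMH", "SMH", "TN"))
  expect_identical(landmark_schemes("midfoot", midfoot_triple = c("VMB", "SMB", "ID")),
                   c("VMB", "SMB", "ID"))
  expect_error(landmark_schemes("midfoot", midfoot_triple = c("XX", "SMH", "TN")),
               "three of")
  expect_error(landmark_schemes("talus"), "talus is excluded")
  expect_length(landmark_schemes(), 4)
})

test_that("fitting the mean shape returns near-zero weights", {
  m <- small_pipeline()$model
  fit <- suppressWarnings(fit_shape(m, target = predict(m), k = 3, penalty = 0))
  expect_lt(fit$data_rmse, 1e-6)
  expect_lt(max(abs(fit$weights)), 1e-4)
  expect_equal(fit$n_modes_used, 3L)
  expect_identical(fit$mode, "full")
})

test_that("an unpenalized full-rank fit reproduces a training member", {
  fx <- small_pipeline()
  m <- fx$model
  k <- ncol(m$modes)
  target <- point_cloud(fx$corr$shapes[[5]])
  fit <- suppressWarnings(fit_shape(m, target = target, k = k, penalty = 0))
  expect_lt(fit$data_rmse, 1e-6)
  expect_lt(max(abs(fit$weights - coef(m)[5, ])), 1e-6)
})

test_that("the fitting objective is non-increasing and the penalty path monotone", {
  fx <- small_pipeline()
  m <- fx$model
  target <- triangle_mesh(fx$corr$shapes[[4]], fx$corr$faces)
  mah <- numeric(0)
  for (p in c(0, 0.01, 0.1, 1, 10)) {
    fit <- suppressWarnings(fit_shape(m, target = target, k = 3, penalty = p))
    expect_true(all(diff(fit$objective) <= 1e-9))
    mah <- c(mah, fit$mahalanobis)
  }
  expect_true(all(diff(mah) <= 1e-9))
  # a heavy penalty degenerates to a rigid fit of the mean
  expect_lt(mah[length(mah)], 1e-6)
  # the default penalty weight is the documented 0.1
  expect_identical(formals(fit_shape)$penalty, 0.1)
})

test_that("sparse fits recover exact landmark data and generating weights", {
  fx <- small_pipeline()
  m <- fx$model
  vidx <- fx$corr$landmark_indices
  # landmarks sampled from the mean shape -> no deformation needed
  mean_pts <- matrix(m$mean, ncol = 3, byrow = TRUE)
  lm0 <- landmark_set("t0", "synthetic", names(vidx), mean_pts[vidx, ])
  f0 <- suppressWarnings(fit_shape(m, landmarks = lm0, penalty = 0))
  expect_lt(f0$data_rmse, 1e-6)
  expect_lt(max(abs(f0$weights)), 1e-4)
  expect_identical(f0$mode, "sparse")

  # landmarks from a synthesized shape with known weights
  b_true <- c(1.2, -0.8, 0.5)
  synth <- predict(m, b_true)$points
  lm1 <- landmark_set("t1", "synthetic", names(vidx), synth[vidx, ])
  f1 <- suppressWarnings(fit_shape(m, landmarks = lm1, k = 3, penalty = 0))
  expect_lt(max(abs(f1$weights - b_true)), 1e-3)
  expect_lt(f1$data_rmse, 1e-4)
})

test_that("noisy landmarks still beat the mean-only reconstruction usually", {
  # population with anatomical variation well above the 1 mm digitization
  # noise, so the landmarks carry usable shape information
  op <- oracle_population(n = 20, sds = c(3, 2.5, 2), noise = 0.05,
                          seed = 35, nv = 400)
  m <- shape_model(op$shapes, landmark_indices = op$tpl$landmark_indices)
  vidx <- m$landmark_indices
  set.seed(33)
  wins <- 0L
  trials <- 50L
  for (t in seq_len(trials)) {
    b_true <- rnorm(3, sd = sqrt(m$evals[1:3]))
    truth <- predict(m, b_true)$points
    noisy <- truth[vidx, ] + matrix(rnorm(9, sd = 1), 3)
    lm <- landmark_set("t", "synthetic", names(vidx), noisy)
    fit <- suppressWarnings(fit_shape(m, landmarks = lm, k = 3, penalty = 0.1))
    rec <- fitted(fit)$points
    err_fit <- sqrt(mean(rowSums((rec - truth)^2)))
    err_mean <- sqrt(mean(rowSums((matrix(m$mean, ncol = 3, byrow = TRUE) - truth)^2)))
    if (err_fit < err_mean) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * trials)
})

test_that("configuration errors are caught", {
  fx <- small_pipeline()
  m <- fx$model
  expect_error(suppressWarnings(fit_shape(m, target = predict(m), k = 99)), "modes")
  expect_error(fit_shape(m), "exactly one")
  expect_error(fit_shape(m, target = predict(m),
                         landmarks = landmark_set("s", "synthetic",
                                                  c("a", "b", "c"), diag(3))),
               "exactly one")
  lm_bad <- landmark_set("s", "synthetic", c("ZZ", "LM2", "LM3"), diag(3))
  expect_error(suppressWarnings(fit_shape(m, landmarks = lm_bad)), "missing")
  expect_error(fit_shape(m, target = predict(m), penalty = -1), "penalty")
})

test_that("reconstruct() returns posed meshes consistent with the fit", {
  fx <- small_pipeline()
  m <- fx$model
  target <- triangle_mesh(fx$corr$shapes[[2]], fx$corr$faces)
  fit <- suppressWarnings(fit_shape(m, target = target, k = 3))
  rec <- reconstruct(fit, as_mesh = TRUE)
  expect_s3_class(rec, "triangle_mesh")
  expect_true(mesh_integrity(rec)$watertight)
  expect_lt(rmse_surface(rec, target), 0.75)
  expect_identical(fitted(fit)$points, rec$vertices)
})
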