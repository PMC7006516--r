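test_that("RBF registration is exact on identity and captures affine change", {
  tpl <- small_pipeline()$tpl$mesh
  pc <- as_point_cloud(tpl)
  r0 <- rbf_register(pc, pc)
  expect_lt(r0$fit_rmse, 1e-9)
  expect_lt(max(abs(r0$warped$points - pc$points)), 1e-6)

  scaled <- pc
  scaled$points <- pc$points * 1.05
  baseline <- sqrt(mean(nearest_neighbour_distances(pc, scaled)^2))
  r1 <- rbf_register(pc, scaled)
  mean_radius <- mean(sqrt(rowSums(scale(pc$points, scale = FALSE)^2)))
  expect_lt(r1$fit_rmse, 0.05 * mean_radius)
  expect_lt(r1$fit_rmse, baseline / 5)
})

test_that("RBF registration tracks a synthetic bone pair at the noise scale", {
  fx <- small_pipeline()
  # two generated subjects, aligned: registration residual should be of the
  # order of the generator's surface noise (0.1 mm), and far below the mode
  # displacement scale
  al <- align_dataset(fx$pop$meshes, fx$pop$landmarks)
  r <- rbf_register(as_point_cloud(al$meshes[[2]]), al$meshes[[3]])
  expect_lt(r$fit_rmse, 2 * 0.25)   # < 2x the noise-scale bound (see vignette)
  expect_gt(r$fit_rmse, 0)
  # regression guard on the registration quality of the cached fixture
  expect_lt(mean(fx$corr$fit_rmse), 0.25)
})

test_that("coincident control points are a reported singularity", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  expect_error(rbf_register(point_cloud(pts), point_cloud(pts), n_control = 5),
               "coincident control points")
})

test_that("ICP recovers known rigid transforms exactly", {
  mesh <- small_pipeline()$tpl$mesh
  src <- as_point_cloud(mesh)
  R <- axis_rotation("y", 15 * pi / 180)
  T_true <- rigid_transform(R, c(2, -1, 3))
  tgt <- apply_transform(src, T_true)
  fit <- icp_register(src, tgt)
  Rhat <- fit$transform$matrix[1:3, 1:3]
  angle_err <- acos(pmin(1, (sum(diag(t(Rhat) %*% R)) - 1) / 2))
  expect_lt(angle_err, 1e-6)
  expect_lt(max(abs(fit$transform$matrix[1:3, 4] - c(2, -1, 3))), 1e-6)
  expect_lt(fit$residual, 1e-9)

  self <- icp_register(src, src)
  expect_lt(max(abs(self$transform$matrix - diag(4))), 1e-9)
})

test_that("ICP residuals are monotonically non-increasing", {
  set.seed(11)
  for (trial in 1:50) {
    n <- sample(30:80, 1)
    src <- random_cloud(n, seed = 100 + trial, scale = 5)
    ang <- runif(3, -0.4, 0.4)
    R <- axis_rotation("z", ang[3]) %*% axis_rotation("y", ang[2]) %*%
      axis_rotation("x", ang[1])
    tgt <- apply_transform(src, rigid_transform(R, runif(3, -3, 3)))
    tgt$points <- tgt$points + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    fit <- icp_register(src, tgt, max_iter = 40)
    expect_true(all(diff(fit$residuals) <= 1e-9))
  }
})

test_that("build_correspondence yields template-ordered, low-error sets", {
  tpl <- small_pipeline()$tpl$mesh
  copies <- list(tpl, tpl, tpl, tpl)
  corr <- build_correspondence(copies)
  expect_true(all(corr$fit_rmse < 1e-9))
  expect_true(all(vapply(corr$shapes, nrow, integer(1)) == nrow(tpl$vertices)))
  expect_equal(corr$fit_rmse[corr$template], 0)

  fx <- small_pipeline()
  expect_true(all(vapply(fx$corr$shapes, nrow, integer(1)) ==
                    nrow(fx$tpl$mesh$vertices)))
  expect_lt(mean(fx$corr$fit_rmse), 0.5)   # well below the mode scale (~1 mm)
  expect_identical(length(fx$corr$shapes), 8L)
})

test_that("farthest-point sampling is deterministic and well spread", {
  pc <- random_cloud(300, seed = 9)
  i1 <- farthest_point_sample(pc, 50, seed = 0)
  i2 <- farthest_point_sample(pc, 50, seed = 0)
  expect_identical(i1, i2)
  expect_identical(anyDuplicated(i1), 0L)
  # greedy farthest-point samples are well spread: the chosen subset's
  # minimum pairwise distance is a decent fraction of the cloud extent
  D <- as.matrix(dist(pc$points[i1, ]))
  diag(D) <- Inf
  expect_gt(min(D), 0.05 * max(dist(pc$points[sample(300, 50)])))
})
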