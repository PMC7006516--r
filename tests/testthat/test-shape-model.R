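test_that("identical training shapes give a degenerate model equal to the shape", {
  s <- random_cloud(30, seed = 20)$points
  m <- shape_model(list(s, s, s, s, s))
  expect_true(all(m$evals < 1e-12))
  expect_equal(matrix(m$mean, ncol = 3, byrow = TRUE), s)
})

test_that("a single known mode is recovered exactly", {
  base <- random_cloud(40, seed = 21)$points
  set.seed(22)
  u <- rnorm(120)
  u <- u / sqrt(sum(u^2))
  b <- c(-2, -1, 0, 1, 2)
  shapes <- lapply(b, function(bi)
    matrix(as.vector(t(base)) + bi * u, ncol = 3, byrow = TRUE))
  m <- shape_model(shapes)
  expect_equal(m$evals[1], var(b), tolerance = 1e-12)
  expect_gt(abs(sum(m$modes[, 1] * u)), 1 - 1e-9)
  expect_true(all(m$evals[-1] < 1e-12))
})

test_that("eigenvalues match an independent covariance-eigendecomposition oracle", {
  op <- oracle_population(n = 10, nv = 400)
  m <- shape_model(op$shapes)
  X <- t(vapply(op$shapes, function(s) as.vector(t(s)), numeric(3 * nrow(op$shapes[[1]]))))
  Xc <- sweep(X, 2, colMeans(X))
  # oracle: eigendecomposition of the M x M Gram matrix (same nonzero spectrum
  # as the 3N x 3N sample covariance)
  ev_oracle <- sort(eigen(Xc %*% t(Xc) / (nrow(X) - 1), only.values = TRUE)$values,
                    decreasing = TRUE)
  k <- length(m$evals)
  expect_lt(max(abs(m$evals - ev_oracle[seq_len(k)])), 1e-9)
})

test_that("modes are orthonormal with deterministic signs and exact projection", {
  m <- small_pipeline()$model
  expect_lt(max(abs(crossprod(m$modes) - diag(ncol(m$modes)))), 1e-9)
  expect_true(all(diff(m$evals) <= 1e-12))
  for (j in seq_len(ncol(m$modes)))
    expect_gt(m$modes[which.max(abs(m$modes[, j])), j], 0)

  # full-rank projection round-trip reproduces a training member
  sc <- coef(m)
  rec <- predict(m, sc[3, ])
  expect_lt(max(abs(rec$points - small_pipeline()$corr$shapes[[3]])), 1e-9)
})

test_that("explained variance ratios normalize, order and select correctly", {
  m <- small_pipeline()$model
  ev <- explained_variance(m)
  expect_equal(sum(ev), 1, tolerance = 1e-12)
  expect_true(all(diff(ev) <= 1e-12))

  expect_equal(select_num_components(c(0.5, 0.2, 0.15, 0.1, 0.05), 0.80), 3L)
  expect_equal(select_num_components(c(4, 3, 2, 1) / 10, 0.4), 1L)
  expect_equal(select_num_components(1.0, 0.99), 1L)
  expect_equal(explained_variance(structure(list(evals = c(4, 3, 2, 1)),
                                            class = "shape_model")),
               c(0.4, 0.3, 0.2, 0.1))
  expect_error(select_num_components(c(0.5, 0.5), 0), "threshold")
})

test_that("shape synthesis is linear about the mean", {
  m <- small_pipeline()$model
  expect_equal(predict(m)$points, matrix(m$mean, ncol = 3, byrow = TRUE))
  b1 <- c(3 * sqrt(m$evals[1]))
  plus <- predict(m, b1)$points
  minus <- predict(m, -b1)$points
  expect_lt(max(abs(plus + minus - 2 * matrix(m$mean, ncol = 3, byrow = TRUE))),
            1e-9)
  expect_error(predict(m, rep(0, ncol(m$modes) + 1)), "modes")
})

test_that("Mahalanobis distance follows the closed form", {
  m <- structure(list(evals = c(4, 1), modes = diag(2)), class = "shape_model")
  expect_equal(shape_mahalanobis(m, c(0, 0)), 0)
  expect_equal(shape_mahalanobis(m, c(2, 1)), sqrt(2))
  expect_equal(shape_mahalanobis(m, sqrt(c(4, 1))), sqrt(2))
  k <- 5
  mk <- structure(list(evals = runif(k, 0.5, 3)), class = "shape_model")
  expect_equal(shape_mahalanobis(mk, sqrt(mk$evals)), sqrt(k))
  m0 <- structure(list(evals = c(1, 0)), class = "shape_model")
  expect_error(shape_mahalanobis(m0, c(1, 1)), "truncate")
})

test_that("the generating mode subspace is recovered from oracle correspondences", {
  op <- oracle_population(n = 20, sds = c(1.1, 1.05, 1.0), noise = 0.1,
                          seed = 31, nv = 400)
  m <- shape_model(op$shapes)
  U <- op$pop$modes
  Un <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  ang <- acos(pmin(svd(crossprod(m$modes[, 1:3], Un))$d, 1)) * 180 / pi
  expect_true(all(ang < 5))
})

test_that("simulate() draws shapes with eigenvalue-scaled spread", {
  m <- small_pipeline()$model
  sims <- simulate(m, nsim = 5, seed = 1, k = 2)
  expect_length(sims, 5)
  W <- attr(sims, "weights")
  expect_identical(dim(W), c(5L, 2L))
  sims2 <- simulate(m, nsim = 5, seed = 1, k = 2)
  expect_identical(attr(sims2, "weights"), W)
})

test_that("shapes of unequal size are rejected", {
  a <- random_cloud(10, seed = 1)$points
  b <- random_cloud(11, seed = 2)$points
  expect_error(shape_model(list(a, a, b)), "correspondence error")
  expect_error(shape_model(list(a, a)), "at least 3")
})
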