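test_that("templates are watertight with analytic volume and well-spread landmarks", {
  for (kind in c("ellipsoid", "metatarsal", "calcaneus", "midfoot")) {
    tpl <- make_template(kind, 642)
    expect_true(mesh_integrity(tpl$mesh)$watertight)
    expect_gt(mesh_volume(tpl$mesh, signed = TRUE), 0)
    V <- tpl$mesh$vertices
    diag_len <- sqrt(sum((apply(V, 2, max) - apply(V, 2, min))^2))
    seps <- dist(V[tpl$landmark_indices, ])
    expect_gt(min(seps), 0.2 * diag_len)
    expect_identical(names(tpl$landmark_indices), c("LM1", "LM2", "LM3"))
  }

  ell <- make_template("ellipsoid", 1500)
  expect_lt(abs(mesh_volume(ell$mesh) - 4 / 3 * pi * 20 * 12 * 10) /
              (4 / 3 * pi * 20 * 12 * 10), 0.01)

  met <- make_template("metatarsal", 642)$mesh
  extents <- apply(met$vertices, 2, function(v) diff(range(v)))
  expect_gt(max(extents) / min(extents), 2)   # elongated long bone

  expect_error(make_template("ellipsoid", 50), "n_vertices")
})

test_that("population sampling is seed-deterministic and honours degenerate settings", {
  tpl <- make_template("ellipsoid", 300)
  p1 <- sample_population(tpl, n_subjects = 5, seed = 99)
  p2 <- sample_population(tpl, n_subjects = 5, seed = 99)
  expect_identical(p1$meshes, p2$meshes)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$landmarks, p2$landmarks)
  expect_error(sample_population(tpl, n_subjects = 3), "seed is mandatory")

  # zero modes, zero noise, zero pose: every subject is the template
  p0 <- sample_population(tpl, n_subjects = 4, mode_sds = c(0, 0, 0),
                          noise_sd = 0, rot_range_deg = 0, trans_range_mm = 0,
                          left_fraction = 0, seed = 1)
  for (m in p0$meshes)
    expect_equal(m$vertices, tpl$mesh$vertices, tolerance = 1e-12)
})

test_that("generating mode fields are orthogonal, unit-RMS and recoverable", {
  tpl <- make_template("metatarsal", 642)
  pop <- sample_population(tpl, n_subjects = 20, mode_sds = c(2, 1, 0.5),
                           noise_sd = 0, seed = 12)
  U <- pop$modes
  G <- crossprod(U)
  N <- nrow(tpl$mesh$vertices)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-9 * N)          # mutual orthogonality
  expect_equal(diag(G), rep(N, 3), tolerance = 1e-9)       # unit RMS displacement

  # the stored ground-truth weights have the requested spread
  expect_lt(abs(sd(pop$truth$b1) - 2) / 2, 0.35)
  expect_lt(abs(sd(pop$truth$b2) - 1) / 1, 0.35)
  sides <- table(factor(pop$truth$side, c("left", "right")))
  expect_identical(sum(sides), 20L)
})

test_that("surface noise follows vertex normals by default", {
  tpl <- make_template("ellipsoid", 500)
  pop <- sample_population(tpl, n_subjects = 3, mode_sds = c(0, 0, 0),
                           noise_sd = 0.5, rot_range_deg = 0,
                           trans_range_mm = 0, left_fraction = 0, seed = 4)
  vn <- footssm:::vertex_normals(tpl$mesh)
  d <- pop$meshes[[1]]$vertices - tpl$mesh$vertices
  tang <- d - vn * rowSums(d * vn)
  expect_lt(sqrt(mean(rowSums(tang^2))), 1e-9)   # purely normal-direction
  expect_gt(sd(rowSums(d * vn)), 0.3)
})

test_that("export/import round-trips a population faithfully", {
  tpl <- make_template("calcaneus", 300)
  pop <- sample_population(tpl, n_subjects = 6, seed = 5)
  dir <- withr::local_tempdir()
  export_population(pop, dir)
  expect_length(list.files(dir, pattern = "\\.stl$"), 6)
  expect_length(list.files(dir, pattern = "\\.xml$"), 6)
  back <- read_population(dir)
  expect_identical(back$subjects, pop$truth$subject)
  expect_identical(back$sides, pop$truth$side)
  expect_equal(back$truth$b1, pop$truth$b1, tolerance = 1e-12)
  for (i in c(1, 4)) {
    expect_equal(sort(back$meshes[[i]]$vertices[, 1]),
                 sort(pop$meshes[[i]]$vertices[, 1]), tolerance = 1e-4)
    expect_equal(back$landmarks[[i]]$coordinates, pop$landmarks[[i]]$coordinates,
                 tolerance = 1e-9)
  }
  # landmark XML coordinates sit on the exported mesh surface
  for (i in 1:6) {
    cp <- closest_on_surface(back$landmarks[[i]]$coordinates, back$meshes[[i]])
    expect_lt(max(cp$distance), 1e-3)
  }
})

test_that("the pipeline identifies the generating mode count at a stable sample size", {
  # At small M the 80% rule is dominated by sample-eigenvalue noise (see the
  # methods vignette); at M = 60 the spectrum is stable enough that the rule
  # recovers the 3 generating modes in the clear majority of runs.
  hits <- 0L
  for (seed in c(21, 22, 23)) {
    tpl <- make_template("metatarsal", 642)
    pop <- sample_population(tpl, n_subjects = 60, seed = seed)
    corr <- suppressWarnings(correspond_dataset(pop$meshes, pop$landmarks))
    if (select_num_components(shape_model(corr), 0.8) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
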