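test_that("rigid transforms apply, compose, invert and preserve distances", {
  pc <- random_cloud(20, seed = 1)
  expect_equal(apply_transform(pc, rigid_transform())$points, pc$points)
  tr <- apply_transform(point_cloud(rbind(c(0, 0, 0), diag(3))),
                        rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(tr$points[1, ], c(1, 2, 3))

  T1 <- rigid_transform(axis_rotation("z", 37 * pi / 180), c(4, -2, 1))
  roundtrip <- apply_transform(apply_transform(pc, T1), invert_transform(T1))
  expect_lt(max(abs(roundtrip$points - pc$points)), 1e-10)

  # pairwise distances preserved across random rigid transforms
  set.seed(2)
  d0 <- dist(pc$points)
  for (i in 1:10) {
    ang <- runif(3, -pi, pi)
    R <- axis_rotation("z", ang[3]) %*% axis_rotation("y", ang[2]) %*%
      axis_rotation("x", ang[1])
    Ti <- rigid_transform(R, runif(3, -50, 50))
    expect_lt(max(abs(dist(apply_transform(pc, Ti)$points) - d0)), 1e-9)
  }
})

test_that("non-rigid matrices are rejected", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "det")   # reflection
  expect_error(rigid_transform(matrix(rnorm(9), 3)), "orthonormal")
  S <- diag(3) * 1.1
  expect_error(rigid_transform(S), "orthonormal")
})

test_that("mirroring is an involution that flips side and preserves volume", {
  pc <- point_cloud(rbind(c(1, 2, 3), c(0, 0, 0), c(-1, 4, 2), c(2, 2, 2)),
                    side = "left")
  m1 <- mirror(pc, "z")
  expect_equal(m1$points[1, ], c(1, 2, -3))
  expect_equal(m1$side, "right")
  expect_equal(mirror(m1, "z")$points, pc$points)

  mesh <- small_pipeline()$tpl$mesh
  mesh$side <- "right"
  mm <- mirror(mesh, "z")
  expect_equal(mm$side, "left")
  expect_lt(abs(mesh_volume(mm, signed = TRUE) - mesh_volume(mesh, signed = TRUE)),
            1e-9 * mesh_volume(mesh))
  d0 <- dist(mesh$vertices[1:50, ])
  expect_lt(max(abs(dist(mm$vertices[1:50, ]) - d0)), 1e-12)
})

test_that("anatomical frames are orthonormal, right-handed and equivariant", {
  fr <- anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(fr$axes, diag(3))

  set.seed(3)
  for (i in 1:5) {
    p <- matrix(rnorm(9, sd = 20), 3)
    fr <- tryCatch(anatomical_frame(p[1, ], p[2, ], p[3, ]),
                   error = function(e) NULL)
    if (is.null(fr)) next
    expect_lt(max(abs(crossprod(fr$axes) - diag(3))), 1e-12)
    expect_lt(max(abs(footssm:::cross3(fr$axes[, 1], fr$axes[, 2]) - fr$axes[, 3])),
              1e-12)
    # equivariance: rotating the landmarks rotates the axes
    R <- axis_rotation("y", 0.7) %*% axis_rotation("x", -0.3)
    pr <- p %*% t(R)
    fr2 <- anatomical_frame(pr[1, ], pr[2, ], pr[3, ])
    expect_lt(max(abs(fr2$axes - R %*% fr$axes)), 1e-9)
  }
  expect_error(anatomical_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("frame_to_transform maps the defining landmarks canonically", {
  expect_equal(frame_to_transform(anatomical_frame(c(0, 0, 0), c(1, 0, 0),
                                                   c(0, 1, 0)))$matrix, diag(4))
  fr <- anatomical_frame(c(5, 0, 0), c(6, 0, 0), c(5, 1, 0))
  expect_equal(frame_to_transform(fr)$matrix[1:3, 4], c(-5, 0, 0))

  p0 <- c(3, -2, 7); p1 <- c(10, 4, 6); p2 <- c(1, 8, 2)
  Tr <- frame_to_transform(anatomical_frame(p0, p1, p2))
  pts <- apply_transform(point_cloud(rbind(p0, p1, p2, c(0, 0, 0))), Tr)$points
  expect_lt(max(abs(pts[1, ])), 1e-9)                      # origin at 0
  expect_lt(max(abs(pts[2, 2:3])), 1e-9)                   # axis point on +x
  expect_gt(pts[2, 1], 0)
})

test_that("voxelization counts match analytic volumes", {
  cube <- box_mesh(10, 10, 10)
  vg <- voxelize(cube, 1)
  expect_identical(sum(vg$occupancy), 1000L)
  # convergence towards the analytic volume at finer voxels
  v025 <- sum(voxelize(cube, 0.25)$occupancy) * 0.25^3
  expect_lt(abs(v025 - 1000) / 1000, 0.02)

  sph <- make_template("ellipsoid", 2000)$mesh
  sph$vertices <- sph$vertices / rep(c(20, 12, 10), each = nrow(sph$vertices)) * 5
  vol <- sum(voxelize(sph, 0.5)$occupancy) * 0.5^3
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)

  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, , drop = FALSE])
  expect_error(voxelize(open_mesh, 1), "watertight")
  expect_error(voxelize(cube, -1), "voxel_size")
})

test_that("nearest-neighbour distances agree with the brute-force oracle", {
  a <- random_cloud(200, seed = 4)
  b <- random_cloud(300, seed = 5)
  expect_lt(max(abs(nearest_neighbour_distances(a, b) - nn_oracle(a, b))), 1e-12)
  expect_equal(nearest_neighbour_distances(a, a), rep(0, 200))
  expect_equal(nearest_neighbour_distances(matrix(c(0, 0, 0), 1, 3),
                                           rbind(c(1, 0, 0), c(0, 2, 0))), 1.0)
})

test_that("closest-on-surface projection is exact for analytic cases", {
  cube <- box_mesh(10, 10, 10)
  q <- rbind(c(5, 5, 12), c(-1, 5, 5), c(5, 5, 5))
  cp <- closest_on_surface(q, cube)
  expect_equal(cp$distance[1:2], c(2, 1))
  expect_equal(cp$point[1, ], c(5, 5, 10))
  # interior point projects to the nearest wall, 5 mm away
  expect_equal(cp$distance[3], 5)
})

test_that("mesh integrity and volume behave on closed and open meshes", {
  cube <- box_mesh(2, 3, 4)
  expect_true(mesh_integrity(cube)$watertight)
  expect_equal(mesh_volume(cube), 24)
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-(1:2), , drop = FALSE])
  chk <- mesh_integrity(open_mesh)
  expect_false(chk$watertight)
  expect_gt(chk$n_boundary_edges, 0)
  # canonical orientation restores positive signed volume
  flipped <- triangle_mesh(cube$vertices, cube$faces[, c(1, 3, 2)])
  expect_lt(mesh_volume(flipped, signed = TRUE), 0)
  expect_equal(mesh_volume(orient_mesh(flipped), signed = TRUE), 24)
})
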