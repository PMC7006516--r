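#' @useDynLib footssm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

VALID_SEGMENTS <- c("first_metatarsal", "midfoot", "calcaneus", "talus", "synthetic")

#' Construct a point cloud
#'
#' A point cloud is an ordered set of 3D vertex coordinates in millimetres.
#' Ordering is significant once correspondence has been established: index
#' `i` refers to the same anatomical location on every corresponded cloud.
#'
#' @param points numeric matrix with one row per point and columns x, y, z (mm).
#' @param label segment identifier, one of `"first_metatarsal"`, `"midfoot"`,
#'   `"calcaneus"`, `"talus"`, `"synthetic"`.
#' @param side `"left"`, `"right"` or `"none"`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, label = "synthetic", side = "none") {
  points <- as_coord_matrix(points)
  if (nrow(points) < 4L)
    stop("a point cloud needs at least 4 points, got ", nrow(points))
  label <- match.arg(label, VALID_SEGMENTS)
  side <- match.arg(side, c("left", "right", "none"))
  structure(list(points = points, label = label, side = side),
            class = "point_cloud")
}

as_coord_matrix <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (!all(is.finite(points)))
    stop("coordinates must all be finite")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, segment '%s', side '%s'\n",
              nrow(x$points), x$label, x$side))
  invisible(x)
}

#' Construct a triangle mesh
#'
#' A triangle surface mesh; `vertices` follow the [point_cloud()] conventions
#' and `faces` index into them (1-based). Meshes used for volumetric
#' operations must be closed (watertight) and consistently oriented.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer F x 3 matrix of vertex indices.
#' @inheritParams point_cloud
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, label = "synthetic", side = "none") {
  vertices <- as_coord_matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) stop("faces must be an F x 3 index matrix")
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range [1, ", nrow(vertices), "]")
  label <- match.arg(label, VALID_SEGMENTS)
  side <- match.arg(side, c("left", "right", "none"))
  structure(list(vertices = vertices, faces = faces, label = label, side = side),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, segment '%s', side '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$label, x$side))
  invisible(x)
}

#' Convert a mesh to the point cloud of its vertices
#' @param mesh a [triangle_mesh()].
#' @return A [point_cloud()] of the mesh vertices, same ordering.
#' @export
as_point_cloud <- function(mesh) {
  if (inherits(mesh, "point_cloud")) return(mesh)
  stopifnot(inherits(mesh, "triangle_mesh"))
  point_cloud(mesh$vertices, label = mesh$label, side = mesh$side)
}

coords_of <- function(x) {
  if (inherits(x, "point_cloud")) x$points
  else if (inherits(x, "triangle_mesh")) x$vertices
  else as_coord_matrix(x)
}

# ---- rigid transforms -------------------------------------------------------

#' Construct a rigid (rotation + translation) transform
#'
#' Stored as a 4x4 homogeneous matrix with rotation block `R`, translation
#' block `t` and bottom row (0,0,0,1). Pure rotations only: `R` must be
#' orthonormal with determinant +1 (mirroring is handled by [mirror()],
#' never encoded in a transform).
#'
#' @param rotation 3x3 rotation matrix, or a full 4x4 homogeneous matrix.
#' @param translation length-3 translation vector (mm), ignored when a 4x4
#'   matrix is given.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.matrix(rotation) && all(dim(rotation) == c(4L, 4L))) {
    m <- rotation
    if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop("invalid homogeneous matrix: bottom row must be (0,0,0,1)")
    rotation <- m[1:3, 1:3]
    translation <- m[1:3, 4]
  }
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("invalid rigid transform: rotation block is not orthonormal")
  if (abs(det(R) - 1) > 1e-9)
    stop("invalid rigid transform: det(R) != +1 (reflections are not rigid)")
  t <- as.numeric(translation)
  if (length(t) != 3L || !all(is.finite(t))) stop("translation must be 3 finite numbers")
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  structure(list(matrix = m), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (4x4 homogeneous):\n")
  print(round(x$matrix, 6))
  invisible(x)
}

rotation_of <- function(T) T$matrix[1:3, 1:3]
translation_of <- function(T) T$matrix[1:3, 4]

#' Invert a rigid transform
#' @param T a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(T) {
  R <- rotation_of(T)
  rigid_transform(t(R), -t(R) %*% translation_of(T))
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()] objects; the result applies `b` first, then `a`.
#' @return A `rigid_transform` equal to `a %*% b`.
#' @export
compose_transforms <- function(a, b) rigid_transform(a$matrix %*% b$matrix)

#' Rotation about a coordinate axis
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE),
    y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE),
    z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

#' Apply a rigid transform to a point cloud or mesh
#'
#' Maps every point p to `R p + t`, preserving ordering, faces, label and side.
#'
#' @param x a [point_cloud()] or [triangle_mesh()].
#' @param T a [rigid_transform()]; non-rigid matrices are rejected at
#'   construction time.
#' @return The transformed object, same class as `x`.
#' @export
apply_transform <- function(x, T) {
  stopifnot(inherits(T, "rigid_transform"))
  R <- rotation_of(T); tr <- translation_of(T)
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- sweep(x$vertices %*% t(R), 2, -tr)
    x
  } else if (inherits(x, "point_cloud")) {
    x$points <- sweep(x$points %*% t(R), 2, -tr)
    x
  } else stop("x must be a point_cloud or triangle_mesh")
}

#' Mirror a point cloud or mesh about a coordinate plane
#'
#' Negates the chosen coordinate for all points and flips the side flag
#' (left bones are mirrored to right-side geometry before model building,
#' matching how left feet are folded into a single-side training set).
#' For meshes, face winding is reversed so the signed volume stays positive.
#'
#' @param x a [point_cloud()] or [triangle_mesh()].
#' @param axis coordinate to negate; default `"z"` (medio-lateral axis of the
#'   anatomical frame, so mirroring is a sagittal-plane reflection).
#' @return The mirrored object, same class as `x`.
#' @export
mirror <- function(x, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  j <- match(axis, c("x", "y", "z"))
  flip <- function(side) switch(side, left = "right", right = "left", "none")
  if (inherits(x, "triangle_mesh")) {
    x$vertices[, j] <- -x$vertices[, j]
    x$faces <- x$faces[, c(1L, 3L, 2L), drop = FALSE]
    x$side <- flip(x$side)
    x
  } else if (inherits(x, "point_cloud")) {
    x$points[, j] <- -x$points[, j]
    x$side <- flip(x$side)
    x
  } else stop("x must be a point_cloud or triangle_mesh")
}

# ---- anatomical frames ------------------------------------------------------

#' Build an anatomical coordinate frame from three landmarks
#'
#' Constructs a right-handed orthonormal frame in the spirit of the
#' standardized segment coordinate systems used in biomechanics: the first
#' axis points from the origin landmark towards `p_axis1`; the third axis is
#' the normal of the plane spanned by the three landmarks; the second
#' completes the right-handed triad.
#'
#' @param p_origin,p_axis1,p_plane three non-collinear 3D points (mm).
#' @return An object of class `anatomical_frame` with fields `origin` and
#'   `axes` (3x3 matrix, axes in columns).
#' @export
anatomical_frame <- function(p_origin, p_axis1, p_plane) {
  p_origin <- as.numeric(p_origin); p_axis1 <- as.numeric(p_axis1)
  p_plane <- as.numeric(p_plane)
  v1 <- p_axis1 - p_origin
  v2 <- p_plane - p_origin
  n <- cross3(v1, v2)
  if (sqrt(sum(n^2)) < 1e-12 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
    stop("degenerate frame: the three landmarks are collinear")
  x <- v1 / sqrt(sum(v1^2))
  z <- n / sqrt(sum(n^2))
  y <- cross3(z, x)
  structure(list(origin = p_origin, axes = cbind(x, y, z, deparse.level = 0)),
            class = "anatomical_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame\n  origin:", paste(round(x$origin, 4), collapse = ", "),
      "\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' World-to-frame rigid transform of an anatomical frame
#'
#' Returns the transform mapping world coordinates into the frame: the frame
#' origin lands on (0,0,0) and the frame axes on the standard basis.
#'
#' @param frame an [anatomical_frame()].
#' @return A [rigid_transform()].
#' @export
frame_to_transform <- function(frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  A <- frame$axes
  rigid_transform(t(A), -t(A) %*% frame$origin)
}

# ---- mesh integrity and volume ---------------------------------------------

#' Check mesh watertightness and orientability
#'
#' A mesh is watertight and consistently oriented when every undirected edge
#' is shared by exactly two faces traversing it in opposite directions.
#'
#' @param mesh a [triangle_mesh()].
#' @return List with `watertight` (logical), `n_boundary_edges`, and
#'   `n_bad_edges` (edges used more than twice or twice in the same direction).
#' @export
mesh_integrity <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  key <- (pmin(from, to) - 1) * as.double(nv) + pmax(from, to)
  dir <- from < to
  tab <- rowsum(cbind(fwd = as.numeric(dir), bwd = as.numeric(!dir)), key)
  ok <- tab[, "fwd"] == 1 & tab[, "bwd"] == 1
  n_boundary <- sum(tab[, "fwd"] + tab[, "bwd"] == 1)
  list(watertight = all(ok),
       n_boundary_edges = n_boundary,
       n_bad_edges = sum(!ok) - n_boundary)
}

assert_watertight <- function(mesh, what = "volumetric operation") {
  chk <- mesh_integrity(mesh)
  if (!chk$watertight)
    stop(sprintf("%s requires a watertight mesh: %d boundary edge(s), %d inconsistent edge(s)",
                 what, chk$n_boundary_edges, chk$n_bad_edges))
  invisible(TRUE)
}

#' Signed and absolute mesh volume
#'
#' Computes the signed volume of a closed mesh by the divergence theorem
#' (sum of signed tetrahedron volumes against the origin). Positive for
#' outward-oriented surfaces.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param signed return the signed value (default `FALSE` returns |V|).
#' @return Volume in cubic millimetres.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  assert_watertight(mesh, "mesh_volume")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  svol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
              a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
              a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  if (signed) svol else abs(svol)
}

#' Canonically orient a mesh (positive signed volume)
#' @param mesh a watertight [triangle_mesh()].
#' @return The mesh, with faces flipped if its signed volume was negative.
#' @export
orient_mesh <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

# ---- voxelization -----------------------------------------------------------

#' Voxelize a closed mesh
#'
#' Rasterizes the solid bounded by a watertight mesh onto a regular grid:
#' a voxel is occupied iff its centre lies inside the surface (strict,
#' half-open convention; parity of ray crossings along +z). The grid covers
#' the mesh bounding box padded by at least one voxel.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param voxel_size voxel edge length in mm (default 0.59, the in-plane
#'   resolution typical of the MRI protocols this tooling targets).
#' @param origin optional grid origin (corner, mm); computed from the mesh
#'   bounding box when `NULL`. Supplying a shared origin/dims pair puts two
#'   meshes on a common grid.
#' @param dims optional integer grid dimensions c(nx, ny, nz).
#' @return An object of class `voxel_grid`: list with `origin`, `voxel_size`,
#'   `dims` and logical `occupancy` array.
#' @export
voxelize <- function(mesh, voxel_size = 0.59, origin = NULL, dims = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is.numeric(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  assert_watertight(mesh, "voxelize")
  bb0 <- apply(mesh$vertices, 2, min)
  bb1 <- apply(mesh$vertices, 2, max)
  if (is.null(origin)) origin <- bb0 - voxel_size
  if (is.null(dims)) dims <- as.integer(ceiling((bb1 - origin) / voxel_size)) + 1L
  if (prod(as.double(dims)) > 2e8)
    stop("voxel grid too large (", paste(dims, collapse = "x"),
         "); increase voxel_size")
  occ <- .nn_voxelize(mesh, origin, voxel_size, dims)
  structure(list(origin = origin, voxel_size = voxel_size, dims = dims,
                 occupancy = occ),
            class = "voxel_grid")
}

.nn_voxelize <- function(mesh, origin, voxel_size, dims) {
  occ <- .voxelize_cpp(mesh$vertices, mesh$faces, as.numeric(origin),
                       voxel_size, dims[1], dims[2], dims[3])
  array(occ, dim = dims)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %s voxels at %.3g mm, %d occupied (%.4g mm^3)\n",
              paste(x$dims, collapse = "x"), x$voxel_size,
              sum(x$occupancy), sum(x$occupancy) * x$voxel_size^3))
  invisible(x)
}

# ---- nearest neighbours -----------------------------------------------------

#' Per-point nearest-neighbour distances between two clouds
#'
#' For every point of `source`, the Euclidean distance to its nearest point
#' in `target`. Exact (exhaustive search in compiled code).
#'
#' @param source,target [point_cloud()]s, meshes, or N x 3 matrices.
#' @return Numeric vector of length `nrow(source)`, millimetres.
#' @export
nearest_neighbour_distances <- function(source, target) {
  .nn_search_cpp(coords_of(source), coords_of(target))$distance
}

nearest_neighbours <- function(source, target) {
  .nn_search_cpp(coords_of(source), coords_of(target))
}

#' Closest points on a mesh surface
#'
#' Projects each query point onto the closest point of the target triangle
#' surface (not merely the nearest vertex), the correspondence used by the
#' non-rigid registration and surface fitting stages.
#'
#' @param query [point_cloud()] or N x 3 matrix of query points.
#' @param mesh target [triangle_mesh()].
#' @return List with `point` (N x 3 matrix of surface points) and
#'   `distance` (mm).
#' @export
closest_on_surface <- function(query, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  .closest_on_mesh_cpp(coords_of(query), mesh$vertices, mesh$faces)
}

# Generic data-side correspondence: surface projection when the target has
# faces, vertex nearest-neighbour otherwise.
correspond_to <- function(query, target) {
  if (inherits(target, "triangle_mesh")) {
    cp <- closest_on_surface(query, target)
    list(point = cp$point, distance = cp$distance)
  } else {
    Tg <- coords_of(target)
    nn <- .nn_search_cpp(coords_of(query), Tg)
    list(point = Tg[nn$index, , drop = FALSE], distance = nn$distance)
  }
}
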