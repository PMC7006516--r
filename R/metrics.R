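# Reconstruction-accuracy metrics: volumetric Jaccard (voxel
# intersection-over-union on a shared grid), symmetric surface RMSE, and
# symmetric Hausdorff distance, all on registered geometry.

#' Volumetric Jaccard index of two registered closed meshes
#'
#' Both meshes are voxelized on one shared grid covering their joint
#' bounding box; the index is occupied-voxel intersection over union.
#' 1 means identical volumes, 0 disjoint.
#'
#' @param a,b watertight [triangle_mesh()]es, already registered in a common
#'   frame.
#' @param voxel_size shared voxel edge length in mm (default 0.59).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(a, b, voxel_size = 0.59) {
  stopifnot(inherits(a, "triangle_mesh"), inherits(b, "triangle_mesh"))
  assert_watertight(a, "jaccard_index")
  assert_watertight(b, "jaccard_index")
  lo <- pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min))
  hi <- pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max))
  origin <- lo - voxel_size
  dims <- as.integer(ceiling((hi - origin) / voxel_size)) + 1L
  va <- voxelize(a, voxel_size, origin = origin, dims = dims)$occupancy
  vb <- voxelize(b, voxel_size, origin = origin, dims = dims)$occupancy
  uni <- sum(va | vb)
  if (uni == 0) return(0)
  sum(va & vb) / uni
}

#' Symmetric surface RMSE between two registered clouds
#'
#' Root-mean-square of the pooled nearest-neighbour distances in both
#' directions (a to b and b to a). Directed variants are available via
#' `direction`.
#'
#' @param a,b [point_cloud()]s or meshes, registered in a common frame.
#' @param direction `"symmetric"` (default), `"ab"` or `"ba"`.
#' @return RMSE in mm.
#' @export
rmse_surface <- function(a, b, direction = c("symmetric", "ab", "ba")) {
  direction <- match.arg(direction)
  d <- switch(direction,
              symmetric = c(nearest_neighbour_distances(a, b),
                            nearest_neighbour_distances(b, a)),
              ab = nearest_neighbour_distances(a, b),
              ba = nearest_neighbour_distances(b, a))
  sqrt(mean(d^2))
}

#' Symmetric Hausdorff distance between two registered clouds
#'
#' `max(max_a min_b d, max_b min_a d)`: the worst-case nearest-neighbour
#' distance, without percentile truncation.
#'
#' @param a,b [point_cloud()]s or meshes, registered in a common frame.
#' @return Distance in mm.
#' @export
hausdorff_distance <- function(a, b) {
  max(max(nearest_neighbour_distances(a, b)),
      max(nearest_neighbour_distances(b, a)))
}

#' Volumetric similarity of a left and a right bone
#'
#' Mirrors the right mesh onto the left side, rigidly aligns it to the left
#' mesh by ICP, and returns the volumetric Jaccard index — the check used to
#' justify pooling mirrored left bones with right bones in one training set.
#'
#' @param left,right watertight [triangle_mesh()]es of the same segment,
#'   opposite sides.
#' @param voxel_size shared grid resolution, mm.
#' @param mirror_axis coordinate negated by the mirroring (default `"z"`).
#' @return Jaccard index in `[0, 1]`.
#' @export
left_right_similarity <- function(left, right, voxel_size = 0.59,
                                  mirror_axis = "z") {
  stopifnot(inherits(left, "triangle_mesh"), inherits(right, "triangle_mesh"))
  m <- mirror(right, axis = mirror_axis)
  icp <- icp_register(m, left)
  aligned <- apply_transform(m, icp$transform)
  jaccard_index(left, aligned, voxel_size = voxel_size)
}
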