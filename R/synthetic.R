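# Synthetic bone-surface populations with known ground truth: a watertight
# template deformed along a small set of orthogonal, smooth displacement
# fields with chosen per-mode SDs, plus optional surface noise, random rigid
# poses and left/right mirroring. This is the test substrate standing in for
# an MRI cohort; every draw is seed-deterministic.

#' Deterministic bone-like template meshes
#'
#' Builds a closed, outward-oriented triangle mesh of a chosen shape family
#' on a latitude/longitude sphere parameterization, together with three
#' named landmark vertices (`LM1`, `LM2`, `LM3`) at well-separated geometric
#' extremes (two ends of the long axis and the top ridge), mimicking
#' head/base/tuberosity landmark placements on real bones.
#'
#' Families: `"ellipsoid"` (semi-axes 20 x 12 x 10 mm); `"metatarsal"`
#' (elongated shaft with flared head and base, elongation > 2);
#' `"calcaneus"` (blocky superellipsoid); `"midfoot"` (multi-lobed solid).
#' All sizes are desk-scale bone dimensions in mm.
#'
#' @param kind shape family.
#' @param n_vertices approximate vertex count (>= 100; the lat/long grid is
#'   rounded to the closest feasible count).
#' @return List with `mesh` (a watertight [triangle_mesh()]) and
#'   `landmark_indices` (named integer vector LM1..LM3).
#' @export
make_template <- function(kind = c("metatarsal", "ellipsoid", "calcaneus", "midfoot"),
                          n_vertices = 642) {
  kind <- match.arg(kind)
  if (n_vertices < 100) stop("n_vertices must be >= 100")
  n_phi <- max(8L, as.integer(round(sqrt(2 * n_vertices))))
  n_theta <- max(4L, as.integer(round((n_vertices - 2) / n_phi)))
  theta <- seq(0, pi, length.out = n_theta + 2)[-c(1, n_theta + 2)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(phi = phi, theta = theta)  # phi fastest
  sx <- cos(g$theta)
  sy <- sin(g$theta) * cos(g$phi)
  sz <- sin(g$theta) * sin(g$phi)
  S <- rbind(c(1, 0, 0), cbind(sx, sy, sz), c(-1, 0, 0))  # poles on the x axis

  V <- switch(kind,
    ellipsoid = cbind(20 * S[, 1], 12 * S[, 2], 10 * S[, 3]),
    metatarsal = {
      flare <- 1 + 0.45 * exp(-((S[, 1] - 0.85) / 0.2)^2) +
                   0.30 * exp(-((S[, 1] + 0.85) / 0.2)^2)
      # elliptical cross-section plus a dorsal tuberosity near the base:
      # real long bones are far from surfaces of revolution, and the
      # asymmetry keeps axial roll identifiable for registration
      V <- cbind(30 * S[, 1], 9.5 * flare * S[, 2], 6.5 * flare * S[, 3])
      bump <- 2.2 * exp(-((V[, 1] + 12) / 7)^2) * pmax(S[, 3], 0)^2
      V[, 3] <- V[, 3] + bump
      V
    },
    calcaneus = {
      p <- 0.72  # < 1 flattens the sphere into a rounded block
      cbind(22 * sign(S[, 1]) * abs(S[, 1])^p,
            14 * sign(S[, 2]) * abs(S[, 2])^p,
            12 * sign(S[, 3]) * abs(S[, 3])^p)
    },
    midfoot = {
      ang <- atan2(S[, 2], S[, 1])
      lobe <- 1 + 0.18 * cos(2 * ang) * (S[, 1]^2 + S[, 2]^2)
      cbind(25 * lobe * S[, 1], 15 * lobe * S[, 2], 9 * S[, 3])
    })

  # faces: top fan, latitude quads split in two, bottom fan
  idx <- function(it, ip) 1L + (it - 1L) * n_phi + ((ip - 1L) %% n_phi) + 1L
  top <- cbind(1L, idx(1, 1:n_phi), idx(1, 2:(n_phi + 1)))
  quads <- do.call(rbind, lapply(seq_len(n_theta - 1L), function(it) {
    a <- idx(it, 1:n_phi); b <- idx(it, 2:(n_phi + 1))
    c_ <- idx(it + 1L, 1:n_phi); d <- idx(it + 1L, 2:(n_phi + 1))
    rbind(cbind(a, c_, b), cbind(b, c_, d))
  }))
  south <- nrow(S)
  bottom <- cbind(south, idx(n_theta, 2:(n_phi + 1)), idx(n_theta, 1:n_phi))
  mesh <- orient_mesh(triangle_mesh(V, rbind(top, quads, bottom),
                                    label = "synthetic"))

  lmi <- c(LM1 = which.max(V[, 1]), LM2 = which.min(V[, 1]),
           LM3 = which.max(V[, 3]))
  diag_len <- sqrt(sum((apply(V, 2, max) - apply(V, 2, min))^2))
  seps <- stats::dist(V[lmi, ])
  if (min(seps) < 0.2 * diag_len)
    stop("internal error: template landmarks are not well separated")
  list(mesh = mesh, landmark_indices = lmi)
}

# Smooth orthonormal displacement fields over the template vertices:
# elongation along x, bending of the long axis, and radial inflation.
# Fields are mutually orthogonal (Gram-Schmidt in 3N space) and normalized
# to unit RMS vertex displacement, so a mode weight of w mm displaces a
# typical vertex by about w mm.
template_mode_fields <- function(V, n_modes = 3) {
  N <- nrow(V)
  ctr <- sweep(V, 2, colMeans(V))
  sx <- stats::sd(ctr[, 1])
  syz <- sqrt(mean(ctr[, 2]^2 + ctr[, 3]^2))
  raw <- list(
    cbind(ctr[, 1] / sx, 0, 0),                        # elongation
    cbind(0, 0, (ctr[, 1] / sx)^2),                    # long-axis bend
    cbind(0, ctr[, 2], ctr[, 3]) / syz)                # thickness inflation
  raw <- raw[seq_len(n_modes)]
  U <- vapply(raw, function(f) as.vector(t(f)), numeric(3 * N))
  for (j in seq_len(ncol(U))) {
    if (j > 1)
      U[, j] <- U[, j] - U[, 1:(j - 1), drop = FALSE] %*%
        crossprod(U[, 1:(j - 1), drop = FALSE], U[, j])
    U[, j] <- U[, j] / sqrt(sum(U[, j]^2))
  }
  U * sqrt(N)   # unit RMS per-vertex displacement
}

vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  vn <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    agg <- rowsum(fn, f[, j])
    vn[as.integer(rownames(agg)), ] <- vn[as.integer(rownames(agg)), ] + agg
  }
  len <- sqrt(rowSums(vn^2))
  vn / ifelse(len > 0, len, 1)
}

#' Sample a synthetic population with known ground truth
#'
#' Subject i is `template + sum_j b_ij * mode_j + noise`, with
#' `b_ij ~ N(0, sd_j^2)`, iid Gaussian noise applied along vertex normals
#' (or isotropically), then a random rigid pose; subjects drawn as left-side
#' are mirrored. Faces are shared with the template, so ground-truth
#' correspondence is known by construction (and withheld from any pipeline
#' under test).
#'
#' Default mode SDs are of comparable magnitude (1.1, 1.05, 1.0 mm): in
#' segment-level bone populations no single anatomical mode dominates — the
#' explained-variance spectrum decays slowly — and comparable per-mode
#' shares keep all generating modes identifiable from realistic sample
#' sizes. Default surface noise is 0.1 mm (10% of the smallest mode SD),
#' emulating segmentation/smoothing jitter well below anatomical variation.
#'
#' @param template list from [make_template()] (or a [triangle_mesh()], in
#'   which case landmark indices are derived from coordinate extremes).
#' @param n_subjects population size.
#' @param mode_sds per-mode coefficient SDs in mm (RMS vertex displacement
#'   per unit weight is 1, so these are per-vertex displacement scales).
#' @param noise_sd iid surface-noise SD in mm.
#' @param noise_direction `"normal"` (along vertex normals, default) or
#'   `"isotropic"`.
#' @param rot_range_deg,trans_range_mm half-ranges of the uniform random
#'   rigid pose (rotations about x, y, z in degrees; translations in mm).
#' @param left_fraction expected fraction of left-side (mirrored) subjects.
#' @param mirror_axis axis negated when mirroring (default `"z"`).
#' @param seed integer seed; mandatory, every draw flows from it.
#' @return An object of class `synthetic_population`: list with `meshes`
#'   (list of posed [triangle_mesh()]es, side set), `landmarks` (list of
#'   [landmark_set()]s with posed coordinates), `truth` (data frame of true
#'   weights, sides, poses), `modes` (3N x J field matrix), `mode_sds`,
#'   `template` (the template list), `seed`.
#' @export
sample_population <- function(template, n_subjects = 20,
                              mode_sds = c(1.1, 1.05, 1.0), noise_sd = 0.1,
                              noise_direction = c("normal", "isotropic"),
                              rot_range_deg = 10, trans_range_mm = 10,
                              left_fraction = 0.5, mirror_axis = "z",
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for population sampling")
  noise_direction <- match.arg(noise_direction)
  if (inherits(template, "triangle_mesh")) {
    V <- template$vertices
    template <- list(mesh = template,
                     landmark_indices = c(LM1 = which.max(V[, 1]),
                                          LM2 = which.min(V[, 1]),
                                          LM3 = which.max(V[, 3])))
  }
  mesh0 <- template$mesh
  lmi <- template$landmark_indices
  V0 <- mesh0$vertices
  N <- nrow(V0)
  J <- length(mode_sds)
  if (any(mode_sds < 0) || noise_sd < 0) stop("SDs must be >= 0")
  U <- template_mode_fields(V0, n_modes = J)
  vn <- vertex_normals(mesh0)

  set.seed(seed)
  meshes <- vector("list", n_subjects)
  lms <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("s%02d", i)
    b <- stats::rnorm(J, sd = mode_sds)
    eps <- if (noise_sd > 0) {
      if (noise_direction == "normal") vn * stats::rnorm(N, sd = noise_sd)
      else matrix(stats::rnorm(3 * N, sd = noise_sd), N, 3)
    } else matrix(0, N, 3)
    Vi <- V0 + matrix(U %*% b, ncol = 3, byrow = TRUE) + eps
    side <- if (stats::runif(1) < left_fraction) "left" else "right"
    mi <- triangle_mesh(Vi, mesh0$faces, label = mesh0$label, side = "right")
    if (side == "left") mi <- mirror(mi, axis = mirror_axis)
    ang <- stats::runif(3, -rot_range_deg, rot_range_deg) * pi / 180
    tr <- stats::runif(3, -trans_range_mm, trans_range_mm)
    R <- axis_rotation("z", ang[3]) %*% axis_rotation("y", ang[2]) %*%
      axis_rotation("x", ang[1])
    pose <- rigid_transform(R, tr)
    mi <- apply_transform(mi, pose)
    meshes[[i]] <- mi
    lms[[i]] <- landmark_set(id, mesh0$label, names(lmi),
                             mi$vertices[lmi, , drop = FALSE])
    truth[[i]] <- data.frame(subject = id, side = side,
                             t(stats::setNames(b, paste0("b", seq_len(J)))),
                             rx = ang[1], ry = ang[2], rz = ang[3],
                             tx = tr[1], ty = tr[2], tz = tr[3],
                             stringsAsFactors = FALSE)
  }
  structure(list(meshes = meshes, landmarks = lms,
                 truth = do.call(rbind, truth), modes = U,
                 mode_sds = mode_sds, noise_sd = noise_sd,
                 template = template, mirror_axis = mirror_axis, seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("synthetic_population: %d subjects, %d vertices, %d modes (SDs %s mm), noise %.3g mm, seed %d\n",
              length(x$meshes), nrow(x$meshes[[1]]$vertices),
              length(x$mode_sds), paste(x$mode_sds, collapse = "/"),
              x$noise_sd, x$seed))
  cat(sprintf("  sides: %d left / %d right\n",
              sum(x$truth$side == "left"), sum(x$truth$side == "right")))
  invisible(x)
}

#' Export a synthetic population to disk
#'
#' Writes one binary STL and one landmark XML per subject, a ground-truth
#' CSV, and a manifest CSV tying them together; the layout is re-importable
#' with [read_population()].
#'
#' @param pop a `synthetic_population` from [sample_population()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_population <- function(pop, out_dir) {
  stopifnot(inherits(pop, "synthetic_population"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(subject = pop$truth$subject, side = pop$truth$side,
                    stl = paste0(pop$truth$subject, ".stl"),
                    landmarks = paste0(pop$truth$subject, "_landmarks.xml"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(pop$meshes)) {
    write_stl(pop$meshes[[i]], file.path(out_dir, man$stl[i]), dialect = "binary")
    write_landmarks(pop$landmarks[[i]], file.path(out_dir, man$landmarks[i]))
  }
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(pop$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read an exported population directory
#'
#' @param dir directory written by [export_population()] (or following its
#'   manifest layout for real data: `manifest.csv` with columns `subject`,
#'   `side`, `stl`, `landmarks`).
#' @param label segment label to attach to the meshes.
#' @return List with `meshes`, `landmarks`, `sides`, `subjects`, and `truth`
#'   (ground-truth data frame when `truth.csv` is present, else `NULL`).
#' @export
read_population <- function(dir, label = "synthetic") {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  meshes <- lapply(seq_len(nrow(man)), function(i)
    read_stl(file.path(dir, man$stl[i]), label = label, side = man$side[i]))
  lms <- lapply(man$landmarks, function(f) read_landmarks(file.path(dir, f)))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  list(meshes = meshes, landmarks = lms, sides = man$side,
       subjects = man$subject, truth = truth)
}
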