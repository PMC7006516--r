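# Shared fixtures, built in code. Everything is deterministic or explicitly
# seeded.

# Axis-aligned closed box [0,a] x [0,b] x [0,c], outward-oriented.
box_mesh <- function(a = 10, b = 10, c = 10, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, b), z = c(0, c)))
  v <- sweep(v, 2, -origin)
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  orient_mesh(triangle_mesh(v, f))
}

# Regular tetrahedron-ish tiny mesh (watertight).
tetra_mesh <- function(scale = 1) {
  v <- scale * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  orient_mesh(triangle_mesh(v, f))
}

random_cloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  point_cloud(matrix(stats::rnorm(3 * n, sd = scale), n, 3))
}

# Brute-force nearest-neighbour oracle (pure R, quadratic).
nn_oracle <- function(src, tgt) {
  S <- if (is.matrix(src)) src else src$points
  T_ <- if (is.matrix(tgt)) tgt else tgt$points
  apply(S, 1, function(p) sqrt(min(colSums((t(T_) - p)^2))))
}

# One small synthetic pipeline fixture per test session, cached.
.fixture_env <- new.env(parent = emptyenv())

small_pipeline <- function() {
  if (is.null(.fixture_env$small)) {
    tpl <- make_template("metatarsal", 642)
    pop <- sample_population(tpl, n_subjects = 8, seed = 7)
    corr <- suppressWarnings(correspond_dataset(pop$meshes, pop$landmarks))
    .fixture_env$small <- list(tpl = tpl, pop = pop, corr = corr,
                               model = shape_model(corr))
  }
  .fixture_env$small
}

# Oracle-corresponded population (no pose, no mirroring): feeds shape_model
# directly with ground-truth correspondence.
oracle_population <- function(n = 20, sds = c(1.1, 1.05, 1.0), noise = 0.05,
                              seed = 7, nv = 400) {
  tpl <- make_template("metatarsal", nv)
  pop <- sample_population(tpl, n_subjects = n, mode_sds = sds,
                           noise_sd = noise, rot_range_deg = 0,
                           trans_range_mm = 0, left_fraction = 0, seed = seed)
  list(tpl = tpl, pop = pop,
       shapes = lapply(pop$meshes, function(m) m$vertices))
}
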