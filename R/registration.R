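# Two-stage correspondence: a non-rigid radial-basis-function warp of the
# template onto each target establishes dense correspondence (the warped
# template keeps the template's point count and ordering), followed by a
# rigid iterative-closest-point refinement.

#' Farthest-point subsample of a cloud
#'
#' Deterministic greedy farthest-point sampling; the first point is drawn
#' with the supplied seed, every later point maximizes the distance to the
#' already-chosen set.
#'
#' @param points N x 3 matrix or [point_cloud()].
#' @param n number of samples (<= N).
#' @param seed integer seed for the starting point (default 0).
#' @return Integer vector of row indices.
#' @export
farthest_point_sample <- function(points, n, seed = 0) {
  P <- coords_of(points)
  N <- nrow(P)
  if (n > N) stop("cannot sample ", n, " control points from ", N, " points")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  first <- sample.int(N, 1)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  idx <- integer(n)
  idx[1] <- first
  d <- sqrt(rowSums(sweep(P, 2, P[first, ])^2))
  for (i in seq_len(n - 1L)) {
    nxt <- which.max(d)
    idx[i + 1L] <- nxt
    d <- pmin(d, sqrt(rowSums(sweep(P, 2, P[nxt, ])^2)))
  }
  idx
}

rbf_kernel_matrix <- function(A, B, kernel, width) {
  # pairwise distances |a_i - b_j|
  D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  switch(kernel,
         tps = D,                                   # 3D polyharmonic spline r
         gaussian = exp(-D2 / (2 * width^2)),
         stop("unknown RBF kernel: ", kernel))
}

#' Non-rigid RBF registration of a template onto a target
#'
#' Iterates nearest-neighbour correspondence, a regularized radial-basis
#' displacement-field solve, and warping, until the fit RMSE stabilizes.
#' The output cloud has exactly the template's point count and ordering, so
#' repeated registration of one template against a training set yields
#' corresponded clouds.
#'
#' The displacement field is `d(p) = c0 + C p + sum_j w_j phi(|p - q_j|)`
#' with control points `q_j` chosen by farthest-point sampling of the
#' template; the affine part absorbs global scaling/shearing trends.
#'
#' @param template,target [point_cloud()]s (or meshes), pre-aligned in a
#'   common anatomical frame.
#' @param kernel `"tps"` (polyharmonic `r`, default, parameter-free) or
#'   `"gaussian"` (width = median control-point spacing).
#' @param n_control number of RBF control points (default 200, capped at N).
#' @param regularization non-negative smoothness weight on the (normalized)
#'   kernel coefficients, scaled so that a weight of 1 balances the kernel
#'   penalty against the whole data term; the affine part is never
#'   penalized. Default 1: strong smoothing that suppresses tangential
#'   drift of the warp while leaving the surface fit intact.
#' @param max_iter,tol iteration cap and RMSE-change convergence tolerance (mm).
#' @param seed seed for the control-point subsample (default 0).
#' @param anchor_idx optional template vertex indices with known target
#'   positions (typically the anatomical landmark vertices); anchors pin the
#'   tangential component of the warp, which plain closest-point
#'   correspondence leaves unconstrained.
#' @param anchor_targets matrix of known target coordinates, one row per
#'   anchor index.
#' @param anchor_weight relative weight of each anchor equation against one
#'   surface-correspondence equation (default 30).
#' @return List with `warped` (a [point_cloud()], template ordering),
#'   `fit_rmse` (mm, root-mean-square nearest-neighbour distance to the
#'   target), `n_iter`, and `converged`.
#' @export
rbf_register <- function(template, target, kernel = c("tps", "gaussian"),
                         n_control = 200, regularization = 1,
                         max_iter = 20, tol = 1e-4, seed = 0,
                         anchor_idx = NULL, anchor_targets = NULL,
                         anchor_weight = 30) {
  kernel <- match.arg(kernel)
  P0 <- coords_of(template)
  n_control <- min(n_control, nrow(P0))
  ci <- farthest_point_sample(P0, n_control, seed = seed)
  Q <- P0[ci, , drop = FALSE]
  dup <- which(duplicated(round(Q, 12)))
  if (length(dup))
    stop("singular RBF system: coincident control points at rows ",
         paste(ci[dup], collapse = ", "))
  Dq <- as.matrix(stats::dist(Q))
  diag(Dq) <- Inf
  width <- stats::median(apply(Dq, 1, min))   # median control-point spacing
  K <- rbf_kernel_matrix(P0, Q, kernel, width)          # N x C basis
  kn <- sqrt(colMeans(K^2))
  K <- sweep(K, 2, kn, "/")                             # unit-RMS basis columns
  Pa <- cbind(1, P0)                                    # affine part
  A <- cbind(K, Pa)
  nC <- ncol(K); nA <- ncol(Pa)
  # ridge on the (normalized) kernel coefficients, scaled so that
  # regularization = 1 weighs the kernel as heavily as the whole data term;
  # the affine part is never penalized
  reg <- matrix(0, nC + nA, nC + nA)
  reg[seq_len(nC), seq_len(nC)] <- regularization * nrow(P0) * diag(nC)
  has_anchors <- !is.null(anchor_idx)
  if (has_anchors) {
    anchor_targets <- as_coord_matrix(anchor_targets)
    stopifnot(length(anchor_idx) == nrow(anchor_targets))
    Aw <- anchor_weight * A[anchor_idx, , drop = FALSE]
    Dw <- anchor_weight * (anchor_targets - P0[anchor_idx, , drop = FALSE])
    AtA <- crossprod(A) + crossprod(Aw) + reg
  } else {
    AtA <- crossprod(A) + reg
  }

  warped <- P0
  best <- list(warped = P0, rmse = Inf)
  prev_rmse <- Inf
  incr <- 0L
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    cor <- correspond_to(warped, target)
    rmse <- sqrt(mean(cor$distance^2))
    if (rmse < best$rmse) best <- list(warped = warped, rmse = rmse)
    if (is.finite(prev_rmse) && abs(prev_rmse - rmse) < tol) {
      converged <- TRUE
      break
    }
    incr <- if (rmse > prev_rmse) incr + 1L else 0L
    if (incr >= 2L) {
      warning("rbf_register: RMSE increased on two consecutive iterations; returning best iterate")
      break
    }
    prev_rmse <- rmse
    D <- cor$point - P0                                   # total displacement targets
    rhs <- crossprod(A, D)
    if (has_anchors) rhs <- rhs + crossprod(Aw, Dw)
    coefs <- solve(AtA, rhs)
    warped <- P0 + A %*% coefs
  }
  # final RMSE of the returned iterate
  final <- sqrt(mean(correspond_to(best$warped, target)$distance^2))
  out_cloud <- if (inherits(template, "point_cloud")) template else as_point_cloud(template)
  out_cloud$points <- best$warped
  list(warped = out_cloud, fit_rmse = final, n_iter = n_iter, converged = converged)
}

#' Closed-form rigid alignment of paired points (Kabsch)
#'
#' Least-squares rotation + translation mapping `source` rows onto matched
#' `target` rows. Reflections arising in the SVD solve are corrected by the
#' determinant sign fix, so the result is always a pure rotation.
#'
#' @param source,target matched N x 3 matrices (row i of source corresponds
#'   to row i of target).
#' @return A [rigid_transform()].
#' @export
kabsch <- function(source, target) {
  S <- as_coord_matrix(source); Tm <- as_coord_matrix(target)
  stopifnot(nrow(S) == nrow(Tm), nrow(S) >= 3)
  cs <- colMeans(S); ct <- colMeans(Tm)
  H <- crossprod(sweep(S, 2, cs), sweep(Tm, 2, ct))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - R %*% cs)
}

#' Rigid iterative-closest-point registration
#'
#' Classic point-to-point ICP: alternate nearest-neighbour matching with the
#' closed-form rigid solve ([kabsch()]) until the RMS residual stops
#' improving. The residual sequence is monotonically non-increasing.
#'
#' @param source,target [point_cloud()]s or meshes, roughly pre-aligned.
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the residual change (mm, default 1e-6).
#' @return List with `transform` (a [rigid_transform()] mapping source onto
#'   target), `residual` (final RMS nearest-neighbour distance, mm),
#'   `residuals` (per-iteration trace), `n_iter`, `converged`.
#' @export
icp_register <- function(source, target, max_iter = 100, tol = 1e-6,
                         multistart = TRUE) {
  S0 <- coords_of(source)
  Tg <- coords_of(target)

  icp_run <- function(Tinit, iters, tol_run) {
    Tcur <- Tinit
    moved <- sweep(S0 %*% t(rotation_of(Tcur)), 2, -translation_of(Tcur))
    trace <- numeric(0)
    prev <- Inf
    converged <- FALSE
    for (it in seq_len(iters)) {
      cor <- correspond_to(moved, target)
      res <- sqrt(mean(cor$distance^2))
      trace <- c(trace, res)
      if (prev - res < tol_run) {
        converged <- TRUE
        break
      }
      prev <- res
      Tcur <- kabsch(S0, cor$point)
      moved <- sweep(S0 %*% t(rotation_of(Tcur)), 2, -translation_of(Tcur))
    }
    final <- sqrt(mean(correspond_to(moved, target)$distance^2))
    list(transform = Tcur, residual = final, residuals = trace,
         n_iter = length(trace), converged = converged)
  }

  # deterministic initializations: identity-with-centroid-shift, plus (when
  # multistart is on) the four proper-rotation alignments of the principal
  # axes — point-to-point ICP alone cannot escape a wrong axial roll on
  # near-symmetric bones
  cs <- colMeans(S0); ct <- colMeans(Tg)
  inits <- list(rigid_transform(diag(3), ct - cs))
  if (multistart) {
    es <- eigen(stats::cov(S0), symmetric = TRUE)$vectors
    et <- eigen(stats::cov(Tg), symmetric = TRUE)$vectors
    if (det(es) < 0) es[, 3] <- -es[, 3]
    if (det(et) < 0) et[, 3] <- -et[, 3]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      F <- diag(c(s1, s2, s1 * s2))          # keeps det = +1
      R0 <- et %*% F %*% t(es)
      inits <- c(inits, list(rigid_transform(R0, ct - R0 %*% cs)))
    }
  }
  probes <- lapply(inits, icp_run, iters = 15L, tol_run = tol)
  best <- probes[[which.min(vapply(probes, `[[`, numeric(1), "residual"))]]
  full <- icp_run(best$transform, max_iter, tol)
  if (full$residual <= best$residual) full else best
}

#' Build dense correspondence across a training set
#'
#' For each target cloud, the template is warped onto it by [rbf_register()]
#' and the warp is refined by [icp_register()]; the resulting clouds all have
#' the template's point count and ordering, with index i denoting the same
#' anatomical location throughout. The template itself is included as a
#' zero-error correspondence.
#'
#' All clouds must be of one segment, one (right) side — left bones are
#' mirrored upstream — and pre-aligned in a common anatomical frame.
#'
#' @param dataset list of [point_cloud()]s or meshes (the template's source
#'   must carry faces if volumetric validation is intended).
#' @param template index (or subject id) of the template shape; default the
#'   first. Template choice biases the model towards that subject's anatomy.
#' @param ids optional subject identifiers, defaults to `s1..sM` or the
#'   dataset names.
#' @param rigid_first apply a whole-cloud rigid ICP before the non-rigid warp
#'   (default `FALSE`: non-rigid first, then rigid, the order used in the
#'   pipeline this package models).
#' @param landmark_indices optional named vertex indices on the template,
#'   propagated to models built from the set.
#' @param anchor_coords optional list (one element per dataset entry) of
#'   measured landmark coordinate matrices, rows ordered like
#'   `landmark_indices`; when present they anchor the non-rigid warp (see
#'   [rbf_register()]).
#' @param procrustes rigidly re-align every corresponded cloud onto the
#'   template by a known-correspondence Kabsch solve before returning
#'   (default `TRUE`). This removes per-subject residual pose — in
#'   particular anatomical-frame error induced by landmark variation — so
#'   that the shape model does not spend variance on rigid motion.
#' @param ... passed to [rbf_register()].
#' @return An object of class `corresponded_set`: list with `shapes` (list of
#'   N x 3 matrices in template ordering), `fit_rmse` per shape, `template`
#'   index, `faces`, `segment`, `ids`, `landmark_indices`, `errors` (per-shape
#'   failure messages, normally empty).
#' @export
build_correspondence <- function(dataset, template = 1L, ids = NULL,
                                 rigid_first = FALSE, landmark_indices = NULL,
                                 anchor_coords = NULL, procrustes = TRUE,
                                 ...) {
  M <- length(dataset)
  if (M < 2L) stop("need at least 2 shapes")
  if (is.null(ids)) ids <- names(dataset)
  if (is.null(ids)) ids <- paste0("s", seq_len(M))
  if (is.character(template)) template <- match(template, ids)
  if (is.na(template) || template < 1 || template > M)
    stop("invalid template choice")
  tmpl <- dataset[[template]]
  tmpl_pc <- as_point_cloud(tmpl)
  faces <- if (inherits(tmpl, "triangle_mesh")) tmpl$faces else NULL
  segment <- tmpl_pc$label

  shapes <- vector("list", M)
  fit_rmse <- rep(NA_real_, M)
  errors <- character(0)
  for (i in seq_len(M)) {
    if (i == template) {
      shapes[[i]] <- tmpl_pc$points
      fit_rmse[i] <- 0
      next
    }
    res <- tryCatch({
      tgt <- dataset[[i]]        # mesh targets enable surface-projection
      src <- tmpl_pc
      if (rigid_first) {
        pre <- icp_register(src, tgt)
        src <- apply_transform(src, pre$transform)
      }
      nr <- if (!is.null(anchor_coords) && !is.null(landmark_indices))
        rbf_register(src, tgt, anchor_idx = unname(landmark_indices),
                     anchor_targets = anchor_coords[[i]], ...)
      else rbf_register(src, tgt, ...)
      ic <- icp_register(nr$warped, tgt)
      warped <- apply_transform(nr$warped, ic$transform)
      list(points = warped$points,
           rmse = sqrt(mean(correspond_to(warped, tgt)$distance^2)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, stats::setNames(conditionMessage(res), ids[i]))
    } else {
      shapes[[i]] <- res$points
      fit_rmse[i] <- res$rmse
    }
  }
  ok <- !vapply(shapes, is.null, logical(1))
  if (!ok[template]) stop("template registration failed")
  if (!all(ok))
    warning("registration failed for: ", paste(ids[!ok], collapse = ", "))
  if (procrustes) {
    tmplS <- shapes[[template]]
    shapes <- lapply(shapes, function(s) {
      if (is.null(s)) return(NULL)
      Tp <- kabsch(s, tmplS)
      sweep(s %*% t(rotation_of(Tp)), 2, -translation_of(Tp))
    })
  }
  structure(list(shapes = shapes[ok], fit_rmse = fit_rmse[ok],
                 template = match(template, which(ok)),
                 faces = faces, segment = segment, ids = ids[ok],
                 landmark_indices = landmark_indices, errors = errors),
            class = "corresponded_set")
}

#' @export
print.corresponded_set <- function(x, ...) {
  cat(sprintf("corresponded_set: %d shapes x %d points (segment '%s')\n",
              length(x$shapes), nrow(x$shapes[[1]]), x$segment))
  cat(sprintf("  registration RMSE: mean %.3g mm, max %.3g mm\n",
              mean(x$fit_rmse), max(x$fit_rmse)))
  invisible(x)
}
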