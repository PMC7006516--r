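# Reconstruction by shape-model fitting: rigid pose (rotation + translation)
# plus deformation along a chosen number of leading modes, with a
# Mahalanobis penalty discouraging implausible deformations.
#
# Objective (both fitting modes):
#     J(T, b) = data_rmse(T, b)  +  penalty * mahalanobis(b)
# where data_rmse is the RMS distance between the posed, deformed model and
# the target data (nearest-neighbour correspondences for full surfaces,
# known correspondences for sparse landmarks). The optimizer alternates
# closed-form solves: correspondence update, rigid Kabsch solve, and a
# majorize-minimize ridge solve for b (with a backtracking safeguard), which
# keeps J non-increasing at every iteration.

#' Built-in sparse landmark schemes per foot segment
#'
#' Returns the named anatomical landmark triple used for sparse
#' reconstruction of a segment: first metatarsal `TL` (lateral head), `TM`
#' (medial head), `TB` (medial base); calcaneus `PT` (peroneal tubercle),
#' `ST` (sustentaculum tali), `CA` (upper central posterior ridge); midfoot
#' defaults to `VMH` (fifth metatarsal head), `SMH` (second metatarsal head),
#' `TN` (navicular tuberosity) from the six conventional midfoot motion
#' capture labels (`VMH`, `SMH`, `VMB`, `SMB`, `ID`, `TN`). The talus has no
#' externally accessible landmarks and is excluded from sparse fitting.
#'
#' @param segment segment label, or `NULL` (default) for the full scheme list.
#' @param midfoot_triple override for the midfoot triple (any three of the
#'   six midfoot labels).
#' @return Character vector of three landmark names (or a named list of all
#'   schemes when `segment` is `NULL`).
#' @export
landmark_schemes <- function(segment = NULL,
                             midfoot_triple = c("VMH", "SMH", "TN")) {
  midfoot_all <- c("VMH", "SMH", "VMB", "SMB", "ID", "TN")
  midfoot_triple <- as.character(midfoot_triple)
  if (length(midfoot_triple) != 3L || !all(midfoot_triple %in% midfoot_all))
    stop("midfoot_triple must be three of: ", paste(midfoot_all, collapse = ", "))
  schemes <- list(first_metatarsal = c("TL", "TM", "TB"),
                  midfoot = midfoot_triple,
                  calcaneus = c("PT", "ST", "CA"),
                  synthetic = c("LM1", "LM2", "LM3"))
  if (is.null(segment)) return(schemes)
  if (identical(segment, "talus"))
    stop("unsupported segment: the talus is excluded from sparse reconstruction ",
         "(no externally accessible anatomical landmarks)")
  if (!segment %in% names(schemes)) stop("unknown segment: ", segment)
  schemes[[segment]]
}

# Majorize-minimize ridge update for the mode weights. Minimizes the local
# quadratic majorizer of  rms(|A b - r|) + penalty * sqrt(sum b^2/lam)
# and backtracks towards b0 if the true objective would increase.
solve_weights <- function(A, r, lam, penalty, b0, n_res) {
  k <- length(lam)
  if (k == 0) return(numeric(0))
  obj <- function(b) {
    e <- r - A %*% b
    sqrt(sum(e^2) / n_res) + penalty * shape_mahalanobis_k(b, lam)
  }
  rmse0 <- {
    e <- r - A %*% b0
    sqrt(sum(e^2) / n_res)
  }
  m0 <- shape_mahalanobis_k(b0, lam)
  AtA <- crossprod(A)
  Atr <- crossprod(A, r)
  lam_safe <- pmax(lam, .Machine$double.xmin)
  ridge_solve <- function(alpha) {
    tryCatch(as.numeric(solve(AtA + diag(alpha / lam_safe, k), Atr)),
             error = function(e) b0)
  }
  # Candidate updates: the norm-penalty majorizer is degenerate at b0 = 0,
  # so try a ladder of effective ridge weights (including the pure
  # least-squares solve) and keep whatever lowers the true objective most,
  # with a backtracking safeguard towards b0.
  alphas <- if (penalty > 0) {
    base <- penalty * n_res * max(rmse0, 1e-12)
    unique(c(0, if (is.finite(m0) && m0 > 1e-10) base / m0,
             base * c(0.01, 0.1, 1, 10)))
  } else 0
  J0 <- obj(b0)
  best_b <- b0
  best_J <- J0
  for (alpha in alphas) {
    b1 <- ridge_solve(alpha)
    step <- 1
    for (i in 1:20) {
      b <- b0 + step * (b1 - b0)
      Jb <- obj(b)
      if (Jb <= J0 + 1e-12) {
        if (Jb < best_J) { best_J <- Jb; best_b <- b }
        break
      }
      step <- step / 2
    }
  }
  best_b
}

#' Fit a shape model to target data
#'
#' Reconstructs a bone geometry by optimizing rigid pose and mode weights
#' against either a full target surface (`target`, nearest-neighbour
#' correspondence) or three named sparse anatomical landmarks (`landmarks`,
#' known correspondence via the model's landmark vertex indices).
#'
#' @param model a [shape_model()].
#' @param target a [point_cloud()] or mesh: the full surface to fit
#'   (mutually exclusive with `landmarks`).
#' @param landmarks a [landmark_set()] of measured landmark coordinates.
#' @param k number of modes to deform along. Defaults to the 80%-variance
#'   count for full fits and to 3 for sparse fits (three landmarks support at
#'   most three uniquely determined weights beyond the six rigid DOF).
#' @param penalty Mahalanobis penalty weight (default 0.1).
#' @param scheme landmark names to use for sparse fits; defaults to the
#'   built-in scheme for the model's segment (see [landmark_schemes()]).
#' @param max_iter,tol outer-iteration cap and convergence tolerance on the
#'   objective. Defaults: 100 and 1e-8 for full fits; 2000 and 1e-12 for
#'   sparse fits (the tiny landmark system alternates cheaply but can
#'   converge slowly when mode displacements at the landmarks resemble
#'   rigid motions).
#' @param init_pose optional [rigid_transform()] initial pose (model to
#'   target space); default: ICP of the model mean onto the target for full
#'   fits, landmark Procrustes for sparse fits.
#' @return An object of class `ssm_fit`: `transform` (model-to-target
#'   [rigid_transform()]), `weights`, `mahalanobis`, `data_rmse` (mm),
#'   `n_modes_used`, `mode` (`"full"` or `"sparse"`), `objective` trace,
#'   `converged`, plus the reconstructed surface via [fitted.ssm_fit()] /
#'   [reconstruct()].
#' @export
fit_shape <- function(model, target = NULL, landmarks = NULL, k = NULL,
                      penalty = 0.1, scheme = NULL, max_iter = NULL,
                      tol = NULL, init_pose = NULL) {
  stopifnot(inherits(model, "shape_model"))
  if (is.null(target) == is.null(landmarks))
    stop("supply exactly one of 'target' (full fit) or 'landmarks' (sparse fit)")
  if (penalty < 0) stop("penalty must be >= 0")
  K <- ncol(model$modes)
  mean_pts <- matrix(model$mean, ncol = 3, byrow = TRUE)

  if (!is.null(target)) {
    mode <- "full"
    if (is.null(max_iter)) max_iter <- 100
    if (is.null(tol)) tol <- 1e-8
    if (is.null(k)) k <- select_num_components(model, 0.8)
    if (k > K) stop("k = ", k, " exceeds the model's ", K, " modes")
    if (is.null(init_pose)) init_pose <- icp_register(mean_pts, target)$transform
    res <- fit_iterate(model, k, penalty, max_iter, tol, init_pose,
                       correspond = function(pts) {
                         cp <- correspond_to(pts, target)
                         list(rows = seq_len(nrow(pts)), y = cp$point)
                       },
                       model_rows = seq_len(model$n_points))
  } else {
    mode <- "sparse"
    if (is.null(max_iter)) max_iter <- 2000
    if (is.null(tol)) tol <- 1e-12
    stopifnot(inherits(landmarks, "landmark_set"))
    if (is.null(k)) k <- min(3L, K)
    if (k > K) stop("k = ", k, " exceeds the model's ", K, " modes")
    if (is.null(scheme)) scheme <- landmark_schemes(model$segment)
    if (is.null(model$landmark_indices))
      stop("model carries no landmark vertex indices; cannot fit sparse data")
    missing_model <- setdiff(scheme, names(model$landmark_indices))
    if (length(missing_model))
      stop("model has no vertex index for landmark(s): ",
           paste(missing_model, collapse = ", "))
    pos <- match(scheme, landmarks$names)
    if (anyNA(pos))
      stop("landmark file is missing: ", paste(scheme[is.na(pos)], collapse = ", "))
    Y <- landmarks$coordinates[pos, , drop = FALSE]
    vidx <- model$landmark_indices[scheme]
    if (is.null(init_pose)) init_pose <- kabsch(mean_pts[vidx, , drop = FALSE], Y)
    res <- fit_iterate(model, k, penalty, max_iter, tol, init_pose,
                       correspond = function(pts) list(rows = seq_len(nrow(pts)), y = Y),
                       model_rows = vidx)
    res <- polish_sparse(res, model, k, penalty, Y, vidx)
  }

  structure(c(res, list(mode = mode, model = model)), class = "ssm_fit")
}

# Shared alternating optimizer. `model_rows` are the model vertex indices
# constrained by data; `correspond(pts)` returns the current data positions
# for those vertices.
fit_iterate <- function(model, k, penalty, max_iter, tol, init_pose,
                        correspond, model_rows) {
  lam <- model$evals[seq_len(k)]
  P <- model$modes[, seq_len(k), drop = FALSE]
  crows <- as.vector(t(outer(3 * (model_rows - 1), 1:3, `+`)))  # stacked rows
  A <- P[crows, , drop = FALSE]
  mu_sub <- matrix(model$mean[crows], ncol = 3, byrow = TRUE)
  n_res <- 3 * length(model_rows)

  b <- numeric(k)
  pose <- init_pose
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    shape_sub <- mu_sub + matrix(A %*% b, ncol = 3, byrow = TRUE)
    posed <- sweep(shape_sub %*% t(rotation_of(pose)), 2, -translation_of(pose))
    cor <- correspond(posed)
    y <- cor$y
    rmse <- sqrt(sum((posed - y)^2) / n_res)
    J <- rmse + penalty * shape_mahalanobis_k(b, lam)
    trace <- c(trace, J)
    if (prev - J < tol) { converged <- TRUE; break }
    prev <- J
    # rigid update on current correspondences
    pose <- kabsch(shape_sub, y)
    # weight update in model space
    yl <- sweep(y, 2, translation_of(pose)) %*% rotation_of(pose)  # R^T (y - t)
    r <- as.vector(t(yl - mu_sub))
    b <- solve_weights(A, r, lam, penalty, b, n_res)
  }
  shape_sub <- mu_sub + matrix(A %*% b, ncol = 3, byrow = TRUE)
  posed <- sweep(shape_sub %*% t(rotation_of(pose)), 2, -translation_of(pose))
  cor <- correspond(posed)
  rmse <- sqrt(sum((posed - cor$y)^2) / n_res)
  if (!converged)
    warning("fit_shape: objective not converged after ", max_iter,
            " iterations; returning best iterate")
  list(transform = pose, weights = b,
       mahalanobis = shape_mahalanobis_k(b, lam),
       data_rmse = rmse, n_modes_used = k, objective = trace,
       converged = converged)
}

shape_mahalanobis_k <- function(b, lam) {
  if (!length(b)) return(0)
  # degenerate (zero-variance) modes: zero weight costs nothing, any other
  # weight is infinitely implausible
  term <- ifelse(lam > 0, b^2 / lam, ifelse(b == 0, 0, Inf))
  sqrt(sum(term))
}

# Gauss-Newton polish of a sparse fit: the alternating solves converge
# slowly when mode displacements at the three landmarks resemble rigid
# motions, so the tiny joint (pose, b) system is finished with a damped
# Gauss-Newton solver (majorize-minimize outer loop for the Mahalanobis
# term). The polished iterate is kept only if it lowers the objective.
polish_sparse <- function(res, model, k, penalty, Y, vidx) {
  lam <- model$evals[seq_len(k)]
  crows <- as.vector(t(outer(3 * (vidx - 1), 1:3, `+`)))
  A <- model$modes[crows, seq_len(k), drop = FALSE]
  mu_sub <- matrix(model$mean[crows], ncol = 3, byrow = TRUE)
  n_res <- length(crows)

  rotvec <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-14) return(diag(3))
    Kx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
                 byrow = TRUE) / th
    diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  }
  pose_pts <- function(R, tr, b) {
    pts <- mu_sub + matrix(A %*% b, ncol = 3, byrow = TRUE)
    sweep(pts %*% t(R), 2, -tr)
  }
  objective <- function(R, tr, b) {
    sqrt(sum((pose_pts(R, tr, b) - Y)^2) / n_res) +
      penalty * shape_mahalanobis_k(b, lam)
  }

  R0 <- rotation_of(res$transform)
  t0 <- translation_of(res$transform)
  b0 <- res$weights
  J_best <- utils::tail(res$objective, 1)

  for (outer in 1:8) {
    m0 <- shape_mahalanobis_k(b0, lam)
    alpha <- if (penalty > 0) {
      rmse0 <- sqrt(sum((pose_pts(R0, t0, b0) - Y)^2) / n_res)
      penalty * n_res * max(rmse0, 1e-12) / max(m0, 1e-8)
    } else 0
    # damped Gauss-Newton on ssd + alpha * sum(b^2/lam) over (w, t, b)
    resid <- function(par) {
      R <- rotvec(par[1:3]) %*% R0
      tr <- t0 + par[4:6]
      b <- par[-(1:6)]
      c(as.vector(pose_pts(R, tr, b) - Y), sqrt(alpha / lam) * b)
    }
    par <- c(rep(0, 6), b0)
    r <- resid(par)
    for (it in 1:40) {
      Jm <- vapply(seq_along(par), function(j) {
        h <- 1e-6 * max(1, abs(par[j]))
        pj <- par; pj[j] <- pj[j] + h
        (resid(pj) - r) / h
      }, numeric(length(r)))
      delta <- tryCatch(solve(crossprod(Jm) + diag(1e-10, ncol(Jm)),
                              -crossprod(Jm, r)),
                        error = function(e) NULL)
      if (is.null(delta)) break
      step <- 1
      improved <- FALSE
      for (ls in 1:20) {
        cand <- par + step * as.numeric(delta)
        rc <- resid(cand)
        if (sum(rc^2) < sum(r^2)) {
          par <- cand; r <- rc; improved <- TRUE; break
        }
        step <- step / 2
      }
      if (!improved || sqrt(sum(delta^2)) < 1e-13) break
    }
    R0 <- rotvec(par[1:3]) %*% R0
    t0 <- t0 + par[4:6]
    b0 <- par[-(1:6)]
    if (penalty == 0) break   # single GN pass is exact for the data term
  }

  J_new <- objective(R0, t0, b0)
  if (!is.finite(J_new) || J_new > J_best + 1e-15) return(res)
  res$transform <- rigid_transform(R0, t0)
  res$weights <- b0
  res$mahalanobis <- shape_mahalanobis_k(b0, lam)
  res$data_rmse <- sqrt(sum((pose_pts(R0, t0, b0) - Y)^2) / n_res)
  res$objective <- c(res$objective, J_new)
  res$converged <- TRUE
  res
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("ssm_fit (%s): k = %d modes, data RMSE %.4g mm, Mahalanobis %.4g\n",
              x$mode, x$n_modes_used, x$data_rmse, x$mahalanobis))
  cat(sprintf("  %d iterations, %s\n", length(x$objective),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.ssm_fit <- function(object, ...) {
  cat(sprintf("Shape-model fit (%s data), segment '%s'\n",
              object$mode, object$model$segment))
  cat(sprintf("  modes used:   %d\n", object$n_modes_used))
  cat(sprintf("  data RMSE:    %.4g mm\n", object$data_rmse))
  cat(sprintf("  Mahalanobis:  %.4g\n", object$mahalanobis))
  cat(sprintf("  weights (b):  %s\n",
              paste(signif(object$weights, 4), collapse = ", ")))
  cat(sprintf("  objective:    %.6g -> %.6g over %d iterations\n",
              object$objective[1], utils::tail(object$objective, 1),
              length(object$objective)))
  invisible(object)
}

#' @export
coef.ssm_fit <- function(object, ...) object$weights

#' Reconstructed surface of a shape-model fit
#'
#' The full model surface synthesized from the fitted mode weights and posed
#' into target space.
#'
#' @param object an `ssm_fit` from [fit_shape()].
#' @param as_mesh return a [triangle_mesh()] (requires template faces on the
#'   model; default when available).
#' @param ... unused.
#' @return A [triangle_mesh()] or [point_cloud()].
#' @export
reconstruct <- function(object, as_mesh = !is.null(object$model$faces), ...) {
  stopifnot(inherits(object, "ssm_fit"))
  pc <- predict(object$model, object$weights)
  out <- apply_transform(pc, object$transform)
  if (as_mesh) triangle_mesh(out$points, object$model$faces,
                             label = object$model$segment)
  else out
}

#' @export
fitted.ssm_fit <- function(object, ...) reconstruct(object, as_mesh = FALSE)

#' @export
residuals.ssm_fit <- function(object, target = NULL, ...) {
  rec <- reconstruct(object, as_mesh = FALSE)
  if (is.null(target)) return(object$data_rmse)
  nearest_neighbour_distances(rec, target)
}
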