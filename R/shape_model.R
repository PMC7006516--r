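# Point-distribution shape models: PCA over corresponded surface point
# clouds. The mean is the arithmetic mean of the stacked 3N-vectors; modes
# and eigenvalues come from the thin SVD of the centred data matrix with
# sample-covariance (1/(M-1)) normalization, so eigenvalues are directly the
# variances of the training scores and Mahalanobis values are well defined.

#' Fit a statistical shape model to corresponded training shapes
#'
#' The central model-building function. Training shapes must be in dense
#' correspondence (same point count, same ordering; see
#' [build_correspondence()]). Each mode (principal component) is an
#' orthonormal 3N-direction; its eigenvalue is the training variance of the
#' corresponding score in mm^2. A deterministic sign convention is applied:
#' the largest-magnitude coefficient of every mode is positive.
#'
#' @param x a `corresponded_set` from [build_correspondence()], or a list of
#'   [point_cloud()]s/matrices with identical dimensions.
#' @param segment segment label stored with the model (taken from the data
#'   when available).
#' @param landmark_indices optional named integer vector mapping landmark
#'   names to model vertex indices (used by sparse fitting).
#' @param ids optional subject identifiers (recycled from the data if present).
#' @return An object of class `shape_model` with elements `mean` (3N vector),
#'   `modes` (3N x K orthonormal matrix), `evals` (non-increasing variances,
#'   mm^2), `scores` (M x K training scores), `n_points`, `n_training`,
#'   `segment`, `landmark_indices`, `faces` (template faces when known),
#'   `ids`.
#' @seealso [predict.shape_model()], [explained_variance()],
#'   [select_num_components()], [fit_shape()]
#' @export
shape_model <- function(x, segment = NULL, landmark_indices = NULL, ids = NULL) {
  faces <- NULL
  if (inherits(x, "corresponded_set")) {
    if (is.null(ids)) ids <- x$ids
    if (is.null(segment)) segment <- x$segment
    if (is.null(landmark_indices)) landmark_indices <- x$landmark_indices
    faces <- x$faces
    shapes <- x$shapes
  } else if (is.list(x)) {
    shapes <- lapply(x, coords_of)
  } else stop("x must be a corresponded_set or a list of corresponded shapes")

  M <- length(shapes)
  if (M < 3L) stop("at least 3 corresponded shapes are required, got ", M)
  n_pts <- vapply(shapes, nrow, integer(1))
  if (length(unique(n_pts)) != 1L)
    stop("correspondence error: shapes have differing point counts (",
         paste(unique(n_pts), collapse = ", "), ")")
  N <- n_pts[1]
  X <- t(vapply(shapes, function(s) as.vector(t(s)), numeric(3L * N)))  # M x 3N
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = min(M, 3L * N), nv = min(M, 3L * N))
  evals <- sv$d^2 / (M - 1)
  keep <- seq_len(min(M - 1L, length(evals)))
  keep <- keep[evals[keep] > max(evals[1], .Machine$double.eps) * 1e-14]
  if (length(keep) == 0) keep <- 1L
  modes <- sv$v[, keep, drop = FALSE]
  evals <- evals[keep]
  # deterministic sign: largest-|coefficient| entry of each mode positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  scores <- Xc %*% modes
  if (is.null(segment)) segment <- "synthetic"
  if (is.null(ids)) ids <- paste0("s", seq_len(M))
  structure(list(mean = mu, modes = modes, evals = evals, scores = scores,
                 n_points = N, n_training = M,
                 segment = match.arg(segment, VALID_SEGMENTS),
                 landmark_indices = landmark_indices, faces = faces,
                 ids = as.character(ids)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  ev <- explained_variance(x)
  cat(sprintf("Statistical shape model ('%s'): %d training shapes, %d points, %d modes\n",
              x$segment, x$n_training, x$n_points, length(x$evals)))
  cat(sprintf("  leading modes explain %s%% of variance\n",
              paste(round(100 * utils::head(ev, 3), 1), collapse = " / ")))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, threshold = 0.8, ...) {
  ev <- explained_variance(object)
  structure(list(segment = object$segment, n_training = object$n_training,
                 n_points = object$n_points, evals = object$evals,
                 ratios = ev, cumulative = cumsum(ev),
                 threshold = threshold,
                 k_at_threshold = select_num_components(object, threshold)),
            class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  cat(sprintf("Statistical shape model of segment '%s'\n", x$segment))
  cat(sprintf("  %d training shapes, %d surface points\n", x$n_training, x$n_points))
  df <- data.frame(mode = seq_along(x$evals),
                   eigenvalue = signif(x$evals, 5),
                   explained = signif(x$ratios, 4),
                   cumulative = signif(x$cumulative, 4))
  print(utils::head(df, 10), row.names = FALSE)
  cat(sprintf("  %d mode(s) reach the %.0f%% variance threshold\n",
              x$k_at_threshold, 100 * x$threshold))
  invisible(x)
}

#' Explained-variance ratios of a shape model
#'
#' @param model a [shape_model()].
#' @return Numeric vector `evals / sum(evals)`, non-increasing; sums to 1 at
#'   full rank.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  model$evals / sum(model$evals)
}

#' Number of modes needed to reach a variance threshold
#'
#' The smallest k whose cumulative explained-variance ratio reaches the
#' threshold — the rule used to pick the mode count for full-surface
#' reconstructions (80% by convention).
#'
#' @param x a [shape_model()] or a vector of explained-variance ratios.
#' @param threshold required cumulative share of variance, in (0, 1];
#'   default 0.8.
#' @return Integer k.
#' @export
select_num_components <- function(x, threshold = 0.8) {
  if (inherits(x, "shape_model")) x <- x$evals
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (sum(x) <= 0) return(1L)   # degenerate: no variance at all
  ratios <- x / sum(x)
  which(cumsum(ratios) >= threshold - 1e-12)[1]
}

#' Synthesize a shape from mode weights
#'
#' Reconstructs `mean + modes[, 1:k] %*% b` for weights `b` of length
#' k <= K. `predict(model)` with no weights returns the mean shape.
#'
#' @param object a [shape_model()].
#' @param weights numeric mode-weight vector `b` (mm, per unit mode).
#' @param ... unused.
#' @return A [point_cloud()] with the model's point count and ordering.
#' @export
predict.shape_model <- function(object, weights = numeric(0), ...) {
  k <- length(weights)
  if (k > ncol(object$modes))
    stop("got ", k, " weights but the model has ", ncol(object$modes), " modes")
  v <- object$mean
  if (k > 0) v <- v + object$modes[, seq_len(k), drop = FALSE] %*% weights
  point_cloud(matrix(v, ncol = 3, byrow = TRUE), label = object$segment)
}

#' Shape synthesized from mode weights, as a mesh
#'
#' @param model a [shape_model()] carrying template faces.
#' @param weights mode-weight vector (see [predict.shape_model()]).
#' @return A [triangle_mesh()].
#' @export
model_mesh <- function(model, weights = numeric(0)) {
  if (is.null(model$faces))
    stop("this shape model carries no template faces")
  pc <- predict(model, weights)
  triangle_mesh(pc$points, model$faces, label = model$segment)
}

#' Training-score matrix of a shape model
#' @param object a [shape_model()].
#' @param ... unused.
#' @return M x K matrix of per-shape mode weights (projections of the
#'   centred training shapes onto the modes).
#' @export
coef.shape_model <- function(object, ...) {
  s <- object$scores
  dimnames(s) <- list(object$ids, paste0("mode", seq_len(ncol(s))))
  s
}

#' Draw random shapes from a shape model
#'
#' Samples mode weights independently as `b_j ~ N(0, lambda_j)` and
#' synthesizes the corresponding surfaces.
#'
#' @param object a [shape_model()].
#' @param nsim number of shapes.
#' @param seed optional integer seed.
#' @param k number of leading modes to sample (default all).
#' @param ... unused.
#' @return List of [point_cloud()]s with attribute `"weights"` (nsim x k).
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL,
                                 k = length(object$evals), ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(stats::rnorm(nsim * k), nsim, k) %*% diag(sqrt(object$evals[seq_len(k)]), k)
  out <- lapply(seq_len(nsim), function(i) predict(object, B[i, ]))
  attr(out, "weights") <- B
  out
}

#' Scree plot of a shape model
#'
#' Per-mode explained variance (bars) with the cumulative curve and the
#' mode-selection threshold overlaid.
#'
#' @param x a [shape_model()].
#' @param n_modes number of leading modes displayed.
#' @param threshold variance threshold drawn as a horizontal line.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.shape_model <- function(x, n_modes = min(9, length(x$evals)),
                             threshold = 0.8, ...) {
  ev <- explained_variance(x)[seq_len(n_modes)]
  bp <- graphics::barplot(100 * ev, names.arg = seq_len(n_modes),
                          xlab = "principal component",
                          ylab = "shape variance explained (%)",
                          ylim = c(0, 100), ...)
  graphics::lines(bp, 100 * cumsum(ev), type = "b", pch = 19)
  graphics::abline(h = 100 * threshold, lty = 2)
  invisible(x)
}

#' Mahalanobis distance of a deformation
#'
#' The standard shape-prior distance `sqrt(sum(b_j^2 / lambda_j))`:
#' how implausible a deformation is relative to the training variance.
#' Used (scaled by a penalty weight, default 0.1) to constrain model
#' deformation during fitting.
#'
#' @param model a [shape_model()].
#' @param weights mode-weight vector `b` (length <= K).
#' @return Non-negative scalar.
#' @export
shape_mahalanobis <- function(model, weights) {
  k <- length(weights)
  if (k > length(model$evals))
    stop("got ", k, " weights but the model has ", length(model$evals), " modes")
  if (k == 0) return(0)
  lam <- model$evals[seq_len(k)]
  if (any(lam <= 0))
    stop("zero eigenvalue among the used modes; truncate to fewer modes")
  sqrt(sum(weights^2 / lam))
}
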