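# Pipeline glue: fold a mixed left/right dataset onto one side, pre-align
# every shape in its anatomical landmark frame, establish correspondence,
# and hand the result to model building and validation.

#' Mirror left-side shapes and align a dataset in landmark frames
#'
#' Left-side meshes (and their landmarks) are mirrored to right-side
#' geometry, then every shape is transformed into the anatomical frame built
#' from its three landmarks (origin at the third landmark, first axis
#' towards the first, plane through the second). This provides the rough
#' common pre-alignment that the registration stage assumes.
#'
#' @param meshes list of [triangle_mesh()]es (the `side` field decides
#'   mirroring).
#' @param landmarks list of [landmark_set()]s, one per mesh, each holding at
#'   least the three `scheme` names.
#' @param scheme three landmark names defining the frame; defaults to the
#'   first three names of the first landmark set.
#' @param mirror_axis axis negated when mirroring lefts (default `"z"`).
#' @return List with `meshes` (aligned, all right-side) and `landmarks`
#'   (aligned landmark sets).
#' @export
align_dataset <- function(meshes, landmarks, scheme = NULL, mirror_axis = "z") {
  stopifnot(length(meshes) == length(landmarks))
  if (is.null(scheme)) scheme <- landmarks[[1]]$names[1:3]
  j <- match(mirror_axis, c("x", "y", "z"))
  out_m <- vector("list", length(meshes))
  out_l <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    lm <- landmarks[[i]]
    pos <- match(scheme, lm$names)
    if (anyNA(pos))
      stop("subject ", lm$subject, " is missing landmark(s): ",
           paste(scheme[is.na(pos)], collapse = ", "))
    P <- lm$coordinates[pos, , drop = FALSE]
    if (identical(m$side, "left")) {
      m <- mirror(m, axis = mirror_axis)
      P[, j] <- -P[, j]
    }
    fr <- anatomical_frame(P[3, ], P[1, ], P[2, ])
    Tr <- frame_to_transform(fr)
    m <- apply_transform(m, Tr)
    R <- rotation_of(Tr); tv <- translation_of(Tr)
    P <- sweep(P %*% t(R), 2, -tv)
    out_m[[i]] <- m
    out_l[[i]] <- landmark_set(lm$subject, lm$segment, scheme, P)
  }
  list(meshes = out_m, landmarks = out_l)
}

#' Run the correspondence stage of the modelling pipeline
#'
#' [align_dataset()] followed by [build_correspondence()]; template landmark
#' vertex indices are located as the template vertices nearest its aligned
#' landmarks, so sparse fitting and validation work downstream.
#'
#' @inheritParams align_dataset
#' @param subjects subject identifiers (defaults to the landmark files').
#' @param template index of the template subject (default 1).
#' @param ... passed to [build_correspondence()] / [rbf_register()].
#' @return A `corresponded_set` (see [build_correspondence()]).
#' @export
correspond_dataset <- function(meshes, landmarks, scheme = NULL,
                               mirror_axis = "z", subjects = NULL,
                               template = 1L, ...) {
  al <- align_dataset(meshes, landmarks, scheme = scheme,
                      mirror_axis = mirror_axis)
  if (is.null(subjects))
    subjects <- vapply(al$landmarks, function(l) l$subject, character(1))
  tmpl_lm <- al$landmarks[[template]]
  nn <- nearest_neighbours(tmpl_lm$coordinates, al$meshes[[template]]$vertices)
  lmi <- stats::setNames(nn$index, tmpl_lm$names)
  build_correspondence(al$meshes, template = template, ids = subjects,
                       landmark_indices = lmi,
                       anchor_coords = lapply(al$landmarks,
                                              function(l) l$coordinates), ...)
}
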