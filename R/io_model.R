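# Shape-model container: versioned JSON. Numeric arrays are serialized at
# full precision (17 significant digits), so save/load round-trips are
# bitwise exact for IEEE doubles.

MODEL_CONTAINER_VERSION <- "1.0"

#' Save a shape model to a JSON container
#'
#' @param model a [shape_model()].
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  payload <- list(
    container = "footssm-shape-model",
    version = MODEL_CONTAINER_VERSION,
    segment = model$segment,
    n_points = model$n_points,
    n_training = model$n_training,
    ids = model$ids,
    mean = model$mean,
    modes = model$modes,
    evals = model$evals,
    scores = model$scores,
    landmark_indices = as.list(model$landmark_indices),
    faces = model$faces)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           matrix = "rowmajor", null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a shape model from a JSON container
#'
#' @param path path written by [save_model()].
#' @return A [shape_model()] object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) stop("corrupt model container: ",
                                               conditionMessage(e)))
  if (!identical(payload$container, "footssm-shape-model"))
    stop("not a footssm shape-model container: ", path)
  if (!identical(payload$version, MODEL_CONTAINER_VERSION))
    stop("model container version mismatch: file has '", payload$version,
         "', this package reads '", MODEL_CONTAINER_VERSION, "'")
  lmi <- NULL
  if (length(payload$landmark_indices)) {
    lmi <- unlist(payload$landmark_indices)
    storage.mode(lmi) <- "integer"
  }
  faces <- payload$faces
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  modes <- as.matrix(payload$modes)
  if (ncol(modes) == 1 && length(payload$evals) == 1) modes <- modes  # K = 1 fine
  structure(list(mean = as.numeric(payload$mean),
                 modes = modes,
                 evals = as.numeric(payload$evals),
                 scores = as.matrix(payload$scores),
                 n_points = as.integer(payload$n_points),
                 n_training = as.integer(payload$n_training),
                 segment = payload$segment,
                 landmark_indices = lmi,
                 faces = faces,
                 ids = as.character(payload$ids)),
            class = "shape_model")
}
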