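# Landmark XML input/output.
#
# Schema (authoritative for this package; an example ships in
# inst/extdata/example_landmarks.xml):
#
#   <landmarks subject="s01" segment="first_metatarsal" units="mm">
#     <landmark name="TL" x="61.2" y="4.1" z="-8.9"/>
#     ...
#   </landmarks>
#
# Landmark names must be unique within a file; coordinates are finite
# millimetre values written at full double precision.

#' Construct a landmark set
#'
#' @param subject subject identifier.
#' @param segment segment label (see [point_cloud()]).
#' @param names character vector of unique landmark names.
#' @param coordinates N x 3 matrix of measured coordinates (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject, segment, names, coordinates) {
  coordinates <- as_coord_matrix_lm(coordinates)
  names <- as.character(names)
  if (length(names) != nrow(coordinates))
    stop("one name per coordinate row required")
  if (anyDuplicated(names))
    stop("duplicate landmark name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  structure(list(subject = as.character(subject),
                 segment = match.arg(segment, VALID_SEGMENTS),
                 names = names, coordinates = coordinates),
            class = "landmark_set")
}

as_coord_matrix_lm <- function(coordinates) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be N x 3")
  if (!all(is.finite(coordinates))) stop("landmark coordinates must be finite")
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  coordinates
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: subject '%s', segment '%s'\n", x$subject, x$segment))
  df <- data.frame(name = x$names, x = x$coordinates[, 1],
                   y = x$coordinates[, 2], z = x$coordinates[, 3])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a landmark XML file
#'
#' @param path path to a landmark XML file (schema above).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "landmarks")
    stop("landmark schema error: root element must be <landmarks>, got <",
         xml2::xml_name(doc), ">")
  subject <- xml2::xml_attr(doc, "subject")
  segment <- xml2::xml_attr(doc, "segment")
  if (is.na(subject) || is.na(segment))
    stop("landmark schema error: <landmarks> needs 'subject' and 'segment' attributes")
  nodes <- xml2::xml_find_all(doc, "./landmark")
  if (length(nodes) == 0) stop("landmark schema error: no <landmark> elements")
  nm <- xml2::xml_attr(nodes, "name")
  xyz <- vapply(c("x", "y", "z"), function(a) {
    v <- xml2::xml_attr(nodes, a)
    if (anyNA(v))
      stop("landmark schema error: missing '", a, "' attribute on landmark(s) ",
           paste(nm[is.na(v)], collapse = ", "))
    as.numeric(v)
  }, numeric(length(nodes)))
  if (anyNA(nm)) stop("landmark schema error: <landmark> without 'name'")
  landmark_set(subject, segment, nm, matrix(xyz, ncol = 3))
}

#' Read a multi-segment landmark XML file
#'
#' A variant document layout groups landmarks of one subject by segment:
#'
#' ```
#' <landmarks subject="s01" units="mm">
#'   <segment label="first_metatarsal">
#'     <landmark name="TL" x="..." y="..." z="..."/>
#'   </segment>
#'   ...
#' </landmarks>
#' ```
#'
#' @param path path to the XML file.
#' @return A named list of [landmark_set()]s, one per segment.
#' @export
read_landmarks_multi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "landmarks")
    stop("landmark schema error: root element must be <landmarks>")
  subject <- xml2::xml_attr(doc, "subject")
  if (is.na(subject)) stop("landmark schema error: missing 'subject'")
  groups <- xml2::xml_find_all(doc, "./segment")
  if (length(groups) == 0)
    stop("landmark schema error: no <segment> groups; use read_landmarks() for flat files")
  out <- list()
  for (g in groups) {
    seg <- xml2::xml_attr(g, "label")
    if (is.na(seg)) stop("landmark schema error: <segment> without 'label'")
    nodes <- xml2::xml_find_all(g, "./landmark")
    nm <- xml2::xml_attr(nodes, "name")
    xyz <- vapply(c("x", "y", "z"), function(a) as.numeric(xml2::xml_attr(nodes, a)),
                  numeric(length(nodes)))
    if (anyNA(nm) || anyNA(xyz))
      stop("landmark schema error in segment '", seg, "'")
    out[[seg]] <- landmark_set(subject, seg, nm, matrix(xyz, ncol = 3))
  }
  out
}

#' Write a landmark XML file
#'
#' Coordinates are serialized at full double precision, so a write/read
#' round-trip is exact.
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  doc <- xml2::xml_new_root("landmarks", subject = lm$subject,
                            segment = lm$segment, units = "mm")
  for (i in seq_along(lm$names)) {
    xml2::xml_add_child(doc, "landmark", name = lm$names[i],
                        x = sprintf("%.17g", lm$coordinates[i, 1]),
                        y = sprintf("%.17g", lm$coordinates[i, 2]),
                        z = sprintf("%.17g", lm$coordinates[i, 3]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
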