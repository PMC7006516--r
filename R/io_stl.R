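# STL surface input/output. Both the ASCII and little-endian binary dialects
# are supported; coordinates are millimetres throughout the package (STL
# itself carries no units). Binary STL stores float32 coordinates, so one
# write/read round-trip quantizes doubles to float32 and is bitwise-stable
# from then on.

#' Read an STL surface file
#'
#' Accepts ASCII and binary STL. Vertices are deduplicated by exact
#' coordinate match (an optional welding tolerance is available), so shared
#' triangle corners become shared mesh vertices.
#'
#' @param path path to an `.stl` file.
#' @param label,side segment metadata attached to the mesh (see
#'   [triangle_mesh()]).
#' @param weld_tolerance optional distance below which vertices are merged;
#'   `0` (default) requires exact coordinate equality, preferred for
#'   reproducibility.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, label = "synthetic", side = "none",
                     weld_tolerance = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 15) stop("malformed STL (file too short): ", path)
  raw_all <- readBin(path, "raw", n = sz)
  head_raw <- raw_all[seq_len(min(sz, 512))]
  nul <- which(head_raw == as.raw(0))      # binary STL payloads contain NULs
  if (length(nul)) head_raw <- head_raw[seq_len(nul[1] - 1L)]
  head_txt <- if (length(head_raw)) rawToChar(head_raw) else ""
  Encoding(head_txt) <- "latin1"
  is_ascii <- grepl("^\\s*solid", head_txt) &&
    (grepl("facet", head_txt, fixed = TRUE) ||
       grepl("endsolid", head_txt, fixed = TRUE) || sz < 84)

  if (!is_ascii) {
    if (sz < 84)
      stop("malformed STL (not ASCII, and too short for a binary header): ", path)
    ntri <- readBin(raw_all[81:84], "integer", size = 4, endian = "little")
    if (ntri < 1) stop("empty STL solid: ", path)
    expected <- 84 + 50 * as.double(ntri)
    if (sz != expected)
      stop(sprintf(
        "malformed binary STL: header declares %d triangles (%d bytes) but file has %d bytes (record mismatch from byte offset 84)",
        ntri, as.integer(expected), as.integer(sz)))
    # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
    idx <- as.vector(outer(1:48, 84 + seq(0, 50 * (ntri - 1), by = 50), `+`))
    floats <- readBin(raw_all[idx], "numeric", n = 12 * ntri, size = 4,
                      endian = "little")
    tri <- matrix(floats, ntri, 12, byrow = TRUE)[, 4:12, drop = FALSE]
    verts_all <- t(matrix(t(tri), nrow = 3))   # 3*ntri rows of x,y,z
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) == 0) stop("empty STL solid: ", path)
    if (length(vlines) %% 3 != 0)
      stop("malformed ASCII STL: vertex count ", length(vlines),
           " is not a multiple of 3")
    vals <- vapply(strsplit(trimws(vlines), "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) stop("malformed ASCII STL vertex line: ", paste(p, collapse = " "))
      v
    }, numeric(3))
    verts_all <- t(vals)                       # one row per facet corner
  }

  if (!all(is.finite(verts_all))) stop("malformed STL: non-finite coordinates")
  key <- if (weld_tolerance > 0) {
    q <- round(verts_all / weld_tolerance)
    paste(q[, 1], q[, 2], q[, 3])
  } else {
    paste(sprintf("%.17g", verts_all[, 1]), sprintf("%.17g", verts_all[, 2]),
          sprintf("%.17g", verts_all[, 3]))
  }
  idx <- match(key, key)                 # first occurrence per unique vertex
  uniq <- !duplicated(key)
  vid <- cumsum(uniq)[idx]
  vertices <- verts_all[uniq, , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  triangle_mesh(vertices, faces, label = label, side = side)
}

#' Write an STL surface file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` (default; compact, float32 coordinates) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
             (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
             (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)

  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "footssm binary STL (mm)"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    rec <- t(cbind(n, a, b, c_))  # 12 float32 per triangle, column-per-face
    for (i in seq_len(nrow(f))) {
      writeBin(rec[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    lines <- c(sprintf("solid %s", mesh$label),
               paste0("  facet normal ", fmt(n), "\n    outer loop\n",
                      "      vertex ", fmt(a), "\n",
                      "      vertex ", fmt(b), "\n",
                      "      vertex ", fmt(c_), "\n    endloop\n  endfacet"),
               sprintf("endsolid %s", mesh$label))
    writeLines(lines, path)
  }
  invisible(path)
}
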