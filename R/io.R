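#' Read and write triangle meshes
#'
#' Meshes are exchanged as binary little-endian PLY (positions stored as
#' float64, faces as uchar count + int32 indices) or ASCII OBJ. OBJ's
#' 1-based face indexing matches the in-memory convention; both round-trip
#' float64 coordinates losslessly (OBJ via 17 significant digits).
#'
#' @param mesh A [tri_mesh()].
#' @param path File path; format chosen by extension (`.ply` or `.obj`).
#' @param label Role tag for the mesh read back.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns a
#'   `tri_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, label = "mesh") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path, label),
         obj = read_obj(path, label),
         stop("unsupported mesh format: .", ext))
}

write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
  if (nrow(mesh$faces) > 0) {
    for (i in seq_len(nrow(mesh$faces))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  }
}

read_ply <- function(path, label = "mesh") {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- nf <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY: header not terminated")
    if (grepl("^element vertex", line))
      nv <- as.integer(strsplit(line, " ")[[1]][3])
    if (grepl("^element face", line))
      nf <- as.integer(strsplit(line, " ")[[1]][3])
    if (line == "end_header") break
  }
  if (is.null(nv) || is.null(nf)) stop("malformed PLY: missing element counts")
  v <- matrix(readBin(con, "double", 3 * nv, size = 8, endian = "little"),
              ncol = 3, byrow = TRUE)
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", 1))
    if (cnt != 3L) stop(sprintf("malformed PLY: face %d has %d vertices", i, cnt))
    f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
  }
  tri_mesh(v, f, label = label)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  if (nrow(mesh$faces) > 0)
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
}

read_obj <- function(path, label = "mesh") {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  parse3 <- function(x, what, conv) {
    parts <- strsplit(trimws(sub("^[vf] +", "", x)), "[ \t]+")
    bad <- which(lengths(parts) != 3L)
    if (length(bad) > 0)
      stop(sprintf("malformed OBJ %s line %d: expected 3 values", what, bad[1]))
    m <- matrix(suppressWarnings(conv(sub("/.*$", "", unlist(parts)))),
                ncol = 3, byrow = TRUE)
    if (any(is.na(m)))
      stop(sprintf("malformed OBJ %s entries: non-numeric value", what))
    m
  }
  v <- parse3(vl, "vertex", as.numeric)
  f <- if (length(fl) > 0) parse3(fl, "face", as.integer) else
    matrix(integer(0), 0, 3)
  tri_mesh(v, f, label = label)  # OBJ is 1-based, as is tri_mesh
}

#' Read and write point clouds and fiducials as CSV
#'
#' Point clouds use header `x,y,z`; fiducials use `id,x,y,z`. Coordinates
#' round-trip at full double precision. Partial targets get a JSON sidecar
#' (`<path>.json`) naming their viewpoint and parent.
#'
#' @param points Tibble/matrix of points, or a [fiducial_set()].
#' @param path CSV path.
#' @return Readers return tibbles ([fiducial_set()] for fiducials); writers
#'   return `path` invisibly.
#' @export
write_points <- function(points, path) {
  pm <- point_matrix(points)
  df <- data.frame(x = pm[, 1], y = pm[, 2], z = pm[, 3])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (inherits(points, "partial_target")) {
    vp <- attr(points, "viewpoint")
    jsonlite::write_json(
      list(viewpoint = list(name = vp$name, position = vp$position),
           parent = attr(points, "parent")),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_points
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path)
  check_xyz_columns(df, path)
  tibble::as_tibble(df)
}

#' @rdname write_points
#' @export
write_fiducials <- function(points, path) {
  stopifnot(inherits(points, "fiducial_set"))
  df <- data.frame(id = points$id,
                   format(as.data.frame(fiducial_matrix(points)),
                          digits = 17, trim = TRUE, scientific = FALSE))
  names(df) <- c("id", "x", "y", "z")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path)
  if (!"id" %in% names(df)) stop("fiducial CSV must have an `id` column")
  check_xyz_columns(df, path)
  fiducial_set(as.character(df$id), as.matrix(df[, c("x", "y", "z")]))
}

check_xyz_columns <- function(df, path) {
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("CSV must have columns x, y, z: ", path)
  for (cn in c("x", "y", "z")) {
    vals <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0)
      stop(sprintf("missing or non-numeric %s coordinate at row %d of %s",
                   cn, bad[1], path))
  }
}

#' Serialize a rigid transform as a homogeneous matrix
#'
#' JSON with a 4 x 4 row-major homogeneous matrix under `"matrix"`.
#'
#' @param transform A [rigid_transform()].
#' @param path JSON path.
#' @return `write_transform` returns `path` invisibly; `read_transform` a
#'   `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  H <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = as.vector(t(H))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  H <- matrix(jsonlite::read_json(path, simplifyVector = TRUE)$matrix,
              4, 4, byrow = TRUE)
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}

#' Export a distance map for colour-mapped viewing
#'
#' Writes per-vertex distances as CSV (`vertex,distance`) and, given the
#' mesh, an ASCII PLY with a per-vertex scalar `quality` property that mesh
#' viewers colour-map.
#'
#' @param dmap A `distance_map` from [nearest_vertex_distance()].
#' @param mesh The generated-target `tri_mesh` the map is aligned to.
#' @param csv_path,ply_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
export_distance_map <- function(dmap, mesh, csv_path = NULL, ply_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(vertex = dmap$vertex, distance = dmap$distance),
                     csv_path, row.names = FALSE, quote = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(ply_path)) {
    con <- file(ply_path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property double x", "property double y", "property double z",
                 "property double quality",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3],
                       dmap$distance), con)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
    written <- c(written, ply_path)
  }
  invisible(written)
}
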