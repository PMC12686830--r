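#' Triangle surface mesh
#'
#' Lightweight S3 container for a triangle mesh: an `n x 3` numeric matrix of
#' vertex positions in millimetres and an `m x 3` integer matrix of 1-based
#' vertex indices per face. The `label` tags the mesh's role in the pipeline
#' (`"source"`, `"ground_truth_target"`, `"generated_target"`, ...).
#'
#' @param vertices Numeric matrix, `n x 3`, columns x/y/z in mm.
#' @param faces Integer matrix, `m x 3`, 1-based vertex indices.
#' @param label Character role tag.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, label = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces, bbox %.1f x %.1f x %.1f mm>\n",
              x$label, nrow(x$vertices), nrow(x$faces),
              bb[1, 2] - bb[1, 1], bb[2, 2] - bb[2, 1], bb[3, 2] - bb[3, 1]))
  invisible(x)
}

#' Vertices of a mesh as a tibble
#'
#' @param x A `tri_mesh`.
#' @param ... Unused.
#' @return A tibble with columns `vertex`, `x`, `y`, `z`.
#' @export
tidy.tri_mesh <- function(x, ...) {
  v <- x$vertices
  tibble::tibble(vertex = seq_len(nrow(v)),
                 x = v[, 1], y = v[, 2], z = v[, 3])
}

#' @export
glance.tri_mesh <- function(x, ...) {
  tibble::tibble(label = x$label,
                 n_vertices = nrow(x$vertices),
                 n_faces = nrow(x$faces),
                 watertight = is_watertight(x),
                 euler = mesh_euler(x))
}

# 3 x 2 matrix of axis ranges
mesh_bbox <- function(mesh) {
  v <- if (inherits(mesh, "tri_mesh")) mesh$vertices else as.matrix(mesh)
  t(apply(v, 2, range))
}

mesh_bbox_diag <- function(mesh) {
  bb <- mesh_bbox(mesh)
  sqrt(sum((bb[, 2] - bb[, 1])^2))
}

mesh_centroid <- function(mesh) {
  v <- if (inherits(mesh, "tri_mesh")) mesh$vertices else as.matrix(mesh)
  colMeans(v)
}

# Undirected edge list, one row per unique edge (i < j)
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Directed half-edge count per undirected edge; watertight manifold <=> all 2
edge_face_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$vertices) + 1) + pmax(e[, 1], e[, 2])
  table(key)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces (closed 2-manifold, no boundary).
#'
#' @param mesh A `tri_mesh`.
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(edge_face_counts(mesh) == 2L)
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed genus-0 surface.
#'
#' @param mesh A `tri_mesh`.
#' @return Integer.
#' @export
mesh_euler <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

# Number of connected components of the vertex graph
mesh_n_components <- function(mesh) {
  g <- mesh_graph(mesh)
  igraph::count_components(g)
}

# igraph over vertices; edges optionally weighted by Euclidean length
mesh_graph <- function(mesh, weighted = FALSE) {
  e <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  if (weighted) {
    w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    igraph::E(g)$weight <- w
  }
  g
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem volume in mm^3; positive for a consistently
#' outward-oriented watertight mesh.
#'
#' @param mesh A [tri_mesh()].
#' @return Signed volume, mm^3.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
        a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Per-face doubled-area vectors (cross products); rows may be zero for
# degenerate faces
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

mesh_face_areas <- function(mesh) {
  sqrt(rowSums(face_cross(mesh)^2)) / 2
}

#' Point containment by generalized winding number
#'
#' Computes the solid-angle winding number of the mesh surface around each
#' query point (Van Oosterom-Strackee per-triangle solid angles summed and
#' divided by 4*pi); a point is inside a watertight, outward-oriented surface
#' when the winding number is close to 1.
#'
#' @param mesh A watertight `tri_mesh`.
#' @param points Numeric matrix `k x 3` of query points.
#' @return Logical vector of length `k`.
#' @export
points_inside_mesh <- function(mesh, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns")
  v <- mesh$vertices; f <- mesh$faces
  va <- v[f[, 1], , drop = FALSE]
  vb <- v[f[, 2], , drop = FALSE]
  vc <- v[f[, 3], , drop = FALSE]
  apply(points, 1, function(p) {
    a <- sweep(va, 2, p); b <- sweep(vb, 2, p); c_ <- sweep(vc, 2, p)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c_^2))
    num <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c_) * lb +
      rowSums(b * c_) * la
    w <- sum(atan2(num, den)) / (2 * pi)
    abs(w) > 0.5
  })
}

# Nearest-neighbour wrapper around the C++ kernel
nearest_neighbours <- function(query, ref) {
  .nn_bruteforce(as.matrix(query), as.matrix(ref))
}
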