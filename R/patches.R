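#' Seed patch of a generated target
#'
#' The initial registration patch: all generated-target vertices within
#' Euclidean distance `delta` of any partial-target point — the region the
#' camera actually observed.
#'
#' @param gen Generated-target `tri_mesh`.
#' @param partial A `partial_target` point cloud.
#' @param delta Capture radius, mm (> 0), default 5.
#' @return Integer vector of vertex indices (non-empty).
#' @export
seed_patch <- function(gen, partial, delta = 5) {
  if (delta <= 0) stop("`delta` must be > 0")
  d <- nearest_neighbours(gen$vertices, point_matrix(partial))$dist
  mask <- which(d <= delta)
  if (length(mask) == 0L)
    stop(sprintf("no vertex lies within delta = %g mm of the partial target; increase delta", delta))
  mask
}

#' Grow nested coverage patches over a surface
#'
#' Expands the seed patch breadth-first over the vertex-adjacency graph of
#' the mesh, producing strictly nested vertex masks whose coverage fractions
#' (|mask| / |vertices|) are approximately evenly spaced from the seed
#' fraction to exactly 1.0. Vertices are admitted in order of BFS distance
#' from the seed set, ties broken by vertex index, so the series respects
#' surface topology rather than Euclidean proximity.
#'
#' @param gen Generated-target `tri_mesh`.
#' @param seed_mask Non-empty integer vector of seed vertex indices.
#' @param n_levels Number of coverage levels (>= 1); the final level always
#'   covers the full vertex set.
#' @return A `coverage_series`: list with `mesh`, `order` (vertex admission
#'   order) and `levels`, a tibble with columns `level`, `coverage`
#'   (fraction) and `mask` (list of integer index vectors).
#' @export
grow_patches <- function(gen, seed_mask, n_levels = 10L) {
  if (length(seed_mask) == 0L) stop("`seed_mask` must be non-empty")
  if (n_levels < 1L) stop("`n_levels` must be >= 1")
  n <- nrow(gen$vertices)
  g <- mesh_graph(gen)
  # multi-source BFS distance via a virtual source joined to every seed
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, rbind(n + 1L, as.integer(seed_mask)))
  d <- as.numeric(igraph::distances(g, v = n + 1L, weights = NA))[seq_len(n)] - 1
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d))
    stop(sprintf("%d vertices (e.g. vertex %d) are in a component unreachable from the seed patch",
                 length(bad), bad[1]))
  }
  ord <- order(d, seq_len(n))
  f0 <- length(seed_mask) / n
  targets <- seq(f0, 1, length.out = n_levels)
  counts <- pmax(round(targets * n), length(seed_mask))
  counts[length(counts)] <- n
  counts <- unique(counts)
  levels <- tibble::tibble(
    level = seq_along(counts),
    coverage = counts / n,
    mask = lapply(counts, function(k) sort(ord[seq_len(k)])))
  structure(list(mesh = gen, order = ord, levels = levels),
            class = "coverage_series")
}

#' @export
print.coverage_series <- function(x, ...) {
  cat(sprintf("<coverage_series: %d levels, coverage %.3f .. %.3f over %d vertices>\n",
              nrow(x$levels), x$levels$coverage[1],
              x$levels$coverage[nrow(x$levels)], nrow(x$mesh$vertices)))
  invisible(x)
}

#' @export
tidy.coverage_series <- function(x, ...) {
  dplyr::mutate(x$levels, n_vertices = lengths(.data$mask),
                mask = NULL)
}

#' Extract the sub-surface induced by a vertex mask
#'
#' Keeps the faces whose three corners are all in the mask, reindexing
#' vertices; mask vertices that end up in no retained face are kept as
#' isolated points, so the patch's vertex set is exactly the mask.
#'
#' @param gen `tri_mesh`.
#' @param mask Non-empty integer vector of vertex indices.
#' @return An open-surface `tri_mesh` (generally not watertight) whose
#'   vertices are `gen$vertices[mask, ]` in mask order.
#' @export
patch_to_mesh <- function(gen, mask) {
  if (length(mask) == 0L) stop("`mask` must be non-empty")
  mask <- sort(unique(as.integer(mask)))
  keep <- rowSums(matrix(gen$faces %in% mask, ncol = 3L)) == 3L
  newid <- integer(nrow(gen$vertices))
  newid[mask] <- seq_along(mask)
  faces <- matrix(newid[gen$faces[keep, , drop = FALSE]], ncol = 3L)
  tri_mesh(gen$vertices[mask, , drop = FALSE], faces,
           label = paste0(gen$label, "_patch"))
}
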