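#' Surface completion interface
#'
#' The completion stage turns a partial intra-operative point cloud into a
#' complete "generated target" surface. Three pluggable generators are
#' provided: a zero-error oracle, a rigid pre-operative prior, and a
#' distance-dependent error model emulating the characteristic behaviour of
#' learned completion — accurate near the visible region, increasingly wrong
#' far from it.
#'
#' @name completion
NULL

new_generated_target <- function(mesh, method, params = list()) {
  mesh$label <- "generated_target"
  structure(list(mesh = mesh, method = method, params = params),
            class = "generated_target")
}

#' @export
print.generated_target <- function(x, ...) {
  cat(sprintf("<generated_target via '%s': %d vertices>\n",
              x$method, nrow(x$mesh$vertices)))
  invisible(x)
}

#' Oracle completion
#'
#' Returns the ground-truth target verbatim: the zero-error baseline against
#' which error propagation is measured.
#'
#' @param partial A `partial_target` (unused beyond provenance).
#' @param gt Ground-truth intra-operative `tri_mesh`.
#' @return A `generated_target` with `method = "oracle"`.
#' @export
complete_oracle <- function(partial, gt) {
  stopifnot(inherits(gt, "tri_mesh"))
  new_generated_target(gt, "oracle",
                       list(parent = attr(partial, "parent")))
}

#' Pre-operative prior completion
#'
#' Models a no-deformation prior: the undeformed pre-operative source is
#' rigidly aligned to the partial target by multi-start ICP and returned as
#' the completed surface. Vertex-correspondent with the source (and hence
#' with the ground truth when both come from the same phantom).
#'
#' @param partial A non-empty `partial_target`.
#' @param source Pre-operative `tri_mesh`.
#' @param n_restarts,seed,max_iter,tol Passed to [multistart_icp()].
#' @return A `generated_target` with `method = "prior"`; the winning
#'   `rigid_result` is stored in `params$alignment`.
#' @export
complete_prior <- function(partial, source, n_restarts = 5L, seed = 1L,
                           max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(source, "tri_mesh"))
  pm <- point_matrix(partial)
  if (nrow(pm) == 0L) stop("partial target is empty")
  # correspondences must run from the subset to the superset: the partial
  # patch is the moving set against the full source surface, and the fitted
  # transform is inverted to carry the source into the intra-operative frame.
  # (The other direction, all source points matched onto a 300-point patch,
  # collapses the source onto the patch.) No centroid pre-alignment: source
  # and target are approximately aligned by protocol.
  fit <- multistart_icp(pm, source$vertices, n_restarts = n_restarts,
                        seed = seed, max_iter = max_iter, tol = tol,
                        center = FALSE)
  if (!fit$converged)
    stop(sprintf("prior alignment did not converge (best rmse %.3g mm)",
                 fit$rmse))
  mesh <- tri_mesh(transform_points(invert_transform(fit$transform),
                                    source$vertices),
                   source$faces, label = source$label)
  new_generated_target(mesh, "prior",
                       list(alignment = fit, parent = attr(partial, "parent")))
}

#' Error-model parameters
#'
#' Parameters of the distance-dependent completion error model.
#'
#' @param length_scale Error growth length scale `lambda`, mm (> 0): the
#'   geodesic distance over which fidelity to the ground truth decays toward
#'   the prior.
#' @param noise_scale Smooth noise amplitude `sigma`, mm (>= 0) applied in
#'   proportion to the local error weight.
#' @param seed Integer seed for the noise.
#' @return An `error_model_params` object.
#' @export
error_model_params <- function(length_scale = 40, noise_scale = 4, seed = 1L) {
  if (!is.finite(length_scale) || length_scale <= 0)
    stop("`length_scale` must be > 0")
  if (!is.finite(noise_scale) || noise_scale < 0)
    stop("`noise_scale` must be >= 0")
  structure(list(length_scale = length_scale, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "error_model_params")
}

#' Distance-dependent error-model completion
#'
#' Simulates the error structure of learned surface completion: vertices
#' near the visible region reproduce the ground truth, vertices far from it
#' drift toward the rigidly aligned pre-operative prior, with smooth
#' correlated noise growing alongside. Per ground-truth vertex `v`,
#' `w(v) = exp(-D(v)/lambda)` where `D(v)` is the graph-geodesic distance
#' (mm along mesh edges) from `v` to the visible seed set (vertices within
#' `delta` of any partial point), and the output vertex is
#' `w * gt(v) + (1-w) * prior(v) + (1-w) * sigma * eps(v)` with `eps` a
#' seeded per-vertex Gaussian field smoothed over 2-ring neighbourhoods.
#' Topology is preserved, so the result is vertex-correspondent with the
#' ground truth.
#'
#' @param partial A `partial_target` cut from the ground truth.
#' @param gt Ground-truth target `tri_mesh`.
#' @param source Pre-operative `tri_mesh`, vertex-correspondent with `gt`.
#' @param params An [error_model_params()].
#' @param delta Seed-set radius, mm (default 5): ground-truth vertices within
#'   `delta` of any partial point count as visible.
#' @param prior Optional precomputed `generated_target` from
#'   [complete_prior()] (to avoid re-running the alignment).
#' @return A `generated_target` with `method = "error_model"`; `params`
#'   carries the geodesic distances `D` and weights `w`.
#' @export
complete_with_error_model <- function(partial, gt, source, params = error_model_params(),
                                      delta = 5, prior = NULL) {
  stopifnot(inherits(gt, "tri_mesh"), inherits(source, "tri_mesh"),
            inherits(params, "error_model_params"))
  if (nrow(gt$vertices) != nrow(source$vertices) ||
      !identical(gt$faces, source$faces))
    stop("`gt` and `source` must be vertex-correspondent (same topology)")
  if (is.null(prior)) prior <- complete_prior(partial, source)
  pv <- prior$mesh$vertices
  if (nrow(pv) != nrow(gt$vertices))
    stop("prior is not vertex-correspondent with `gt`")

  seed_mask <- which(nearest_neighbours(gt$vertices, point_matrix(partial))$dist <= delta)
  if (length(seed_mask) == 0L)
    stop("partial target does not touch the generated surface (empty seed set)")
  D <- geodesic_to_set(gt, seed_mask)
  w <- exp(-D / params$length_scale)

  eps <- smooth_vertex_noise(gt, params$seed)
  v <- w * gt$vertices + (1 - w) * pv + (1 - w) * params$noise_scale * eps
  mesh <- tri_mesh(v, gt$faces, label = "generated_target")
  new_generated_target(mesh, "error_model",
                       list(model = params, delta = delta, D = D, w = w,
                            parent = attr(partial, "parent")))
}

# graph-geodesic distance (mm along edges) from every vertex to a seed set;
# a zero-weight virtual source attached to every seed turns the multi-source
# problem into one Dijkstra run
geodesic_to_set <- function(mesh, seed_vertices) {
  g <- mesh_graph(mesh, weighted = TRUE)
  n <- nrow(mesh$vertices)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, rbind(n + 1L, seed_vertices),
                         attr = list(weight = rep(0, length(seed_vertices))))
  as.numeric(igraph::distances(g, v = n + 1L))[seq_len(n)]
}

# per-vertex standard-normal 3-vectors smoothed over 2-ring neighbourhoods
# and rescaled to unit component variance, so noise_scale sets the amplitude
smooth_vertex_noise <- function(mesh, seed) {
  n <- nrow(mesh$vertices)
  e <- mesh_edges(mesh)
  eps <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  deg <- tabulate(c(e[, 1], e[, 2]), n)
  for (pass in 1:2) {  # two 1-ring averaging passes = 2-ring support
    acc <- eps
    acc[sort(unique(e[, 1])), ] <- acc[sort(unique(e[, 1])), , drop = FALSE] +
      rowsum(eps[e[, 2], , drop = FALSE], e[, 1])
    acc[sort(unique(e[, 2])), ] <- acc[sort(unique(e[, 2])), , drop = FALSE] +
      rowsum(eps[e[, 1], , drop = FALSE], e[, 2])
    eps <- acc / (deg + 1)
  }
  eps / stats::sd(as.vector(eps))
}
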