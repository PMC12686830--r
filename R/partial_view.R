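#' Camera viewpoint
#'
#' A named position outside the surface from which the intra-operative camera
#' observes the liver.
#'
#' @param position Length-3 numeric, mm.
#' @param name Label, e.g. `"vp1"`.
#' @return A `viewpoint` object.
#' @export
viewpoint <- function(position, name) {
  if (length(position) != 3L || any(!is.finite(position)))
    stop("`position` must be a finite 3-vector")
  structure(list(position = as.numeric(position), name = name),
            class = "viewpoint")
}

#' Five canonical viewpoints around a phantom
#'
#' Places five deterministic camera positions at 1.5 times the
#' bounding-sphere radius from the centroid, mirroring the five regions a
#' laparoscopic camera typically covers: front of the right lobe (`vp1`),
#' back of the right lobe (`vp2`), the left lobe from the back (`vp3`),
#' centrally above (`vp4`), and front of the left lobe (`vp5`). "Front" is
#' -y, "above" is +z (anterior), and the right lobe sits at negative x.
#'
#' @param mesh A `tri_mesh`.
#' @return List of five [viewpoint()]s named `vp1`...`vp5`.
#' @export
make_viewpoints <- function(mesh) {
  ctr <- mesh_centroid(mesh)
  rad <- sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
  dirs <- rbind(
    vp1 = c(-0.60, -0.50, 0.62),
    vp2 = c(-0.60,  0.50, 0.62),
    vp3 = c( 0.60,  0.50, 0.62),
    vp4 = c( 0.00,  0.00, 1.00),
    vp5 = c( 0.60, -0.50, 0.62))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  out <- lapply(rownames(dirs), function(nm) {
    viewpoint(ctr + 1.5 * rad * dirs[nm, ], nm)
  })
  names(out) <- rownames(dirs)
  out
}

#' Remove the posterior surface with a slicing plane
#'
#' Keeps the vertices above the horizontal plane
#' `z = z_min + plane_offset * (z_max - z_min)`, emulating the removal of the
#' camera-inaccessible posterior liver surface. `plane_offset = 0` places the
#' plane below the mesh and retains everything.
#'
#' @param mesh A `tri_mesh`.
#' @param plane_offset Fraction of the z-range in [0, 1); default 0.5.
#' @return Tibble with columns `vertex` (index into `mesh`), `x`, `y`, `z`.
#' @export
slice_posterior <- function(mesh, plane_offset = 0.5) {
  if (plane_offset < 0 || plane_offset >= 1)
    stop("`plane_offset` must lie in [0, 1)")
  zr <- range(mesh$vertices[, 3])
  level <- if (plane_offset == 0) zr[1] - 1e-9 * max(1, diff(zr)) else
    zr[1] + plane_offset * diff(zr)
  keep <- which(mesh$vertices[, 3] > level)
  if (length(keep) == 0L)
    stop(sprintf("plane_offset = %g leaves no anterior vertices", plane_offset))
  tibble::tibble(vertex = keep,
                 x = mesh$vertices[keep, 1],
                 y = mesh$vertices[keep, 2],
                 z = mesh$vertices[keep, 3])
}

#' Downsample a point cloud
#'
#' Farthest-point sampling: the first point is drawn by the seed, each
#' subsequent point maximizes the distance to the already-selected set
#' (ties to the lowest index). Spatially uniform, deterministic per seed, and
#' always a subset of the input. `method = "random"` is a plain seeded
#' subsample for ablation.
#'
#' @param points Tibble or matrix with columns/coordinates `x`, `y`, `z`
#'   (extra columns are carried through).
#' @param n Target size (> 0); if `n >=` input size the input is returned.
#' @param seed Integer seed.
#' @param method `"fps"` (default) or `"random"`.
#' @return The selected rows, in selection order for `"fps"`.
#' @export
downsample_anterior <- function(points, n = 1000L, seed = 1L, method = c("fps", "random")) {
  method <- match.arg(method)
  pm <- point_matrix(points)
  if (nrow(pm) == 0L) stop("input point cloud is empty")
  if (n <= 0L) stop("`n` must be > 0")
  if (n >= nrow(pm)) return(points)
  sel <- if (method == "random") {
    with_seed(seed, sort(sample.int(nrow(pm), n)))
  } else {
    fps_indices(pm, n, seed)
  }
  points[sel, , drop = FALSE]
}

fps_indices <- function(pm, n, seed) {
  first <- with_seed(seed, sample.int(nrow(pm), 1L))
  sel <- integer(n)
  sel[1] <- first
  d2 <- rowSums(sweep(pm, 2, pm[first, ])^2)
  for (i in seq_len(n - 1L)) {
    nxt <- which.max(d2)  # ties: lowest index
    sel[i + 1L] <- nxt
    d2 <- pmin(d2, rowSums(sweep(pm, 2, pm[nxt, ])^2))
  }
  sel
}

point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 3L)
    m <- points[, 1:3, drop = FALSE]
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    m <- as.matrix(points[, c("x", "y", "z")])
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Select the points visible from a viewpoint
#'
#' Keeps the `k` points nearest the viewpoint (ties broken by input order),
#' the distance-based visibility proxy used for partial-target simulation.
#' With the defaults of the pipeline (anterior cloud of 1000, `k = 300`) the
#' partial target covers 30% of the anterior surface.
#'
#' @param points Anterior point cloud (tibble with `x`, `y`, `z` or matrix).
#' @param vp A [viewpoint()].
#' @param k Number of points (>= 1); `k >` cloud size returns the whole cloud.
#' @param parent Label of the ground-truth target the cloud was cut from.
#' @return A `partial_target`: tibble `x`, `y`, `z` (plus carried columns)
#'   with attributes `viewpoint` and `parent`.
#' @export
select_visible <- function(points, vp, k = 300L, parent = "target") {
  stopifnot(inherits(vp, "viewpoint"))
  if (k < 1L) stop("`k` must be >= 1")
  pm <- point_matrix(points)
  d <- sqrt(rowSums(sweep(pm, 2, vp$position)^2))
  k <- min(k, nrow(pm))
  sel <- order(d, seq_along(d))[seq_len(k)]
  out <- tibble::as_tibble(as.data.frame(points[sel, , drop = FALSE]))
  class(out) <- c("partial_target", class(out))
  attr(out, "viewpoint") <- vp
  attr(out, "parent") <- parent
  out
}

#' Simulate a partial intra-operative target
#'
#' The full visibility pipeline: slice off the posterior surface, downsample
#' the anterior cloud to `n_anterior` points by farthest-point sampling, then
#' keep the `k` points nearest the viewpoint.
#'
#' @param mesh Ground-truth intra-operative `tri_mesh`.
#' @param vp A [viewpoint()].
#' @param n_anterior Anterior downsampling target (default 1000).
#' @param k Visible point count (default 300, ~30% of the anterior cloud).
#' @param plane_offset Posterior slicing plane offset (default 0.5).
#' @param seed Integer seed for the downsampling.
#' @return A `partial_target` tibble (see [select_visible()]).
#' @export
simulate_partial_target <- function(mesh, vp, n_anterior = 1000L, k = 300L,
                                    plane_offset = 0.5, seed = 1L) {
  anterior <- slice_posterior(mesh, plane_offset)
  ds <- downsample_anterior(anterior, n_anterior, seed)
  select_visible(ds, vp, k, parent = mesh$label)
}
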