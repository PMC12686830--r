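#' Occupancy field
#'
#' A scalar field assigning each 3D point an occupancy probability in [0, 1],
#' together with the iso-level `threshold` and the dense evaluation grid used
#' for surface extraction. The field abstracts any implicit shape
#' representation whose `threshold`-superlevel set is the solid.
#'
#' @param evaluator Function taking an `n x 3` matrix and returning `n`
#'   occupancy probabilities in [0, 1].
#' @param bbox 3 x 2 matrix of axis ranges (mm) to grid over.
#' @param threshold Iso-level `c` in (0, 1). The default 0.4 is the value
#'   commonly tuned for occupancy-network outputs.
#' @param grid_resolution Grid points per axis (>= 16).
#' @return An `occupancy_field` object.
#' @export
occupancy_field <- function(evaluator, bbox, threshold = 0.4,
                            grid_resolution = 64L) {
  stopifnot(is.function(evaluator))
  bbox <- as.matrix(bbox)
  if (!all(dim(bbox) == c(3L, 2L)) || any(bbox[, 2] <= bbox[, 1]))
    stop("`bbox` must be a 3 x 2 matrix of increasing ranges")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must lie in (0, 1)")
  grid_resolution <- as.integer(grid_resolution)
  if (grid_resolution < 16L) stop("`grid_resolution` must be >= 16")
  structure(list(evaluator = evaluator, bbox = bbox, threshold = threshold,
                 grid_resolution = grid_resolution),
            class = "occupancy_field")
}

#' Extract a watertight mesh from an occupancy field
#'
#' Evaluates the field on a dense regular grid and extracts the iso-surface at
#' the field's threshold with a marching-tetrahedra scheme: each grid cell is
#' split into six positively oriented tetrahedra, iso-vertices are placed by
#' linear interpolation along crossed tetrahedron edges and welded via global
#' edge keys, and each triangle is wound so its normal points from the
#' occupied side outward. The result is a closed 2-manifold whenever the
#' superlevel set is compact strictly inside the grid box.
#'
#' @param field An [occupancy_field()].
#' @param label Role tag for the resulting mesh.
#' @return A watertight [tri_mesh()].
#' @export
extract_mesh_from_occupancy <- function(field, label = "isosurface") {
  stopifnot(inherits(field, "occupancy_field"))
  n <- field$grid_resolution
  xs <- seq(field$bbox[1, 1], field$bbox[1, 2], length.out = n)
  ys <- seq(field$bbox[2, 1], field$bbox[2, 2], length.out = n)
  zs <- seq(field$bbox[3, 1], field$bbox[3, 2], length.out = n)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  vals <- field$evaluator(grid)
  if (length(vals) != nrow(grid) || any(!is.finite(vals)))
    stop("evaluator must return one finite value per grid point")
  if (any(vals < -1e-9) || any(vals > 1 + 1e-9))
    stop("evaluator values must lie in [0, 1]")
  iso_from_grid(grid, vals, c(n, n, n), field$threshold, label = label)
}

# Iso-surface a scalar field sampled on a regular grid (points in
# x-fastest order). Errors when the superlevel set is empty or touches the
# grid boundary (open surface), never returns a broken mesh.
iso_from_grid <- function(points, values, dims, level, label = "isosurface") {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # nudge exact hits off the level so interpolation weights stay in (0,1)
  eps <- 1e-9 * max(1, abs(level))
  values[abs(values - level) < eps] <- level + eps
  inside <- values > level
  if (!any(inside)) stop("iso-surface is empty: no grid value exceeds the level")
  idx3 <- arrayInd(which(inside), .dim = c(nx, ny, nz))
  if (any(idx3 == 1L) || any(idx3[, 1] == nx) || any(idx3[, 2] == ny) ||
      any(idx3[, 3] == nz))
    stop("iso-surface touches the grid boundary; enlarge the bounding box")

  # corner indices (1-based, x-fastest layout) for every cell
  cx <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cy <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  cz <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  base <- (cz - 1L) * nx * ny + (cy - 1L) * nx + cx  # corner (0,0,0)
  o <- c(0L, 1L, 1L + nx, nx, nx * ny, 1L + nx * ny, 1L + nx + nx * ny, nx + nx * ny)
  # cube corners 1..8: (0,0,0)(1,0,0)(1,1,0)(0,1,0)(0,0,1)(1,0,1)(1,1,1)(0,1,1)
  corner <- function(k) base + o[k]

  # keep only cells with a sign change among their 8 corners
  ins <- matrix(FALSE, length(base), 8L)
  for (k in 1:8) ins[, k] <- inside[corner(k)]
  cnt <- rowSums(ins)
  act <- which(cnt > 0L & cnt < 8L)
  if (length(act) == 0L) stop("iso-surface is degenerate: no crossed cells")
  base <- base[act]; ins <- ins[act, , drop = FALSE]

  # six positively oriented tetrahedra per cube along the 1-7 diagonal
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tri_a <- integer(0); tri_b <- integer(0); tri_c <- integer(0)
  tin <- integer(0)  # an interior (occupied) tet vertex per triangle
  tout <- integer(0) # an exterior tet vertex per triangle
  edge_key <- function(i, j) pmin(i, j) * (nx * ny * nz + 1) + pmax(i, j)

  for (t in 1:6) {
    gi <- cbind(base + o[tets[t, 1]], base + o[tets[t, 2]],
                base + o[tets[t, 3]], base + o[tets[t, 4]])
    im <- cbind(ins[, tets[t, 1]], ins[, tets[t, 2]],
                ins[, tets[t, 3]], ins[, tets[t, 4]])
    ni <- rowSums(im)
    for (nk in 1:3) {
      rows <- which(ni == nk)
      if (length(rows) == 0L) next
      gir <- gi[rows, , drop = FALSE]
      imr <- im[rows, , drop = FALSE]
      if (nk == 1L || nk == 3L) {
        # one vertex on the minority side; triangle on its three edges
        target <- if (nk == 1L) imr else !imr
        apex_col <- max.col(target, ties.method = "first")
        for (ac in 1:4) {
          rr <- which(apex_col == ac)
          if (length(rr) == 0L) next
          apex <- gir[rr, ac]
          others <- gir[rr, setdiff(1:4, ac), drop = FALSE]
          tri_a <- c(tri_a, edge_key(apex, others[, 1]))
          tri_b <- c(tri_b, edge_key(apex, others[, 2]))
          tri_c <- c(tri_c, edge_key(apex, others[, 3]))
          if (nk == 1L) { tin <- c(tin, apex); tout <- c(tout, others[, 1]) }
          else          { tin <- c(tin, others[, 1]); tout <- c(tout, apex) }
        }
      } else {
        # two in, two out: quad split into two triangles
        pcol <- max.col(imr, ties.method = "first")
        qcol <- max.col(imr, ties.method = "last")
        rcol <- max.col(!imr, ties.method = "first")
        scol <- max.col(!imr, ties.method = "last")
        rix <- seq_len(nrow(gir))
        p <- gir[cbind(rix, pcol)]; q <- gir[cbind(rix, qcol)]
        r <- gir[cbind(rix, rcol)]; s <- gir[cbind(rix, scol)]
        e_pr <- edge_key(p, r); e_ps <- edge_key(p, s)
        e_qs <- edge_key(q, s); e_qr <- edge_key(q, r)
        tri_a <- c(tri_a, e_pr, e_pr)
        tri_b <- c(tri_b, e_ps, e_qs)
        tri_c <- c(tri_c, e_qs, e_qr)
        tin <- c(tin, p, p); tout <- c(tout, r, r)
      }
    }
  }

  # weld iso-vertices by grid-edge key
  keys <- unique(c(tri_a, tri_b, tri_c))
  pos <- match(c(tri_a, tri_b, tri_c), keys)
  m <- length(tri_a)
  faces <- cbind(pos[1:m], pos[m + 1:m], pos[2 * m + 1:m])

  big <- nx * ny * nz + 1
  i1 <- floor(keys / big); i2 <- keys - i1 * big
  f1 <- values[i1]; f2 <- values[i2]
  tt <- (level - f1) / (f2 - f1)
  verts <- points[i1, , drop = FALSE] +
    tt * (points[i2, , drop = FALSE] - points[i1, , drop = FALSE])

  # orient every triangle outward: normal must point from the occupied tet
  # vertex toward the unoccupied one
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  cc <- verts[faces[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  dirv <- points[tout, , drop = FALSE] - points[tin, , drop = FALSE]
  flip <- rowSums(nrm * dirv) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]

  mesh <- tri_mesh(verts, faces, label = label)
  if (!is_watertight(mesh))
    stop("extracted surface is not watertight; refine the grid")
  mesh
}

#' Enclosed volume of a superlevel set by voxel counting
#'
#' Counts grid cells whose centre exceeds the threshold; a cheap volume proxy
#' used for threshold comparisons.
#'
#' @param field An [occupancy_field()].
#' @param threshold Iso-level to use (defaults to the field's own).
#' @return Volume in mm^3.
#' @export
occupancy_volume <- function(field, threshold = field$threshold) {
  n <- field$grid_resolution
  step <- (field$bbox[, 2] - field$bbox[, 1]) / n
  xs <- field$bbox[1, 1] + (seq_len(n) - 0.5) * step[1]
  ys <- field$bbox[2, 1] + (seq_len(n) - 0.5) * step[2]
  zs <- field$bbox[3, 1] + (seq_len(n) - 0.5) * step[3]
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  vals <- field$evaluator(grid)
  sum(vals > threshold) * prod(step)
}
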