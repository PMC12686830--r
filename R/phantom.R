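#' Synthetic two-lobed liver phantom
#'
#' Builds a watertight liver-like surface as the iso-surface of a smooth
#' implicit union of two overlapping ellipsoidal lobes: a larger "right" lobe
#' and a smaller "left" lobe, blended with a log-sum-exp smooth maximum so
#' the surface is C1. The bounding box is roughly 200 x 150 x 80 mm, the
#' scale of an adult human liver. The anterior side faces +z, the posterior
#' side -z (this fixes the slicing convention for the partial-view
#' simulator). The seed perturbs lobe centres and semi-axes by a few percent
#' so distinct phantoms differ in shape.
#'
#' @param seed Integer seed; the mesh is bit-identical for a fixed seed and
#'   resolution.
#' @param resolution Grid points per axis for iso-surface extraction
#'   (>= 32; below that the two lobes are not reliably resolved).
#' @return A watertight, single-component, genus-0 [tri_mesh()] labelled
#'   `"source"`.
#' @export
make_liver_mesh <- function(seed = 1L, resolution = 64L) {
  resolution <- as.integer(resolution)
  if (resolution < 32L)
    stop("`resolution` must be >= 32 to resolve both lobes")
  shape <- liver_shape_params(seed)
  f <- liver_implicit(shape)
  bbox <- rbind(c(-115, 115), c(-90, 90), c(-55, 55))
  xs <- seq(bbox[1, 1], bbox[1, 2], length.out = resolution)
  ys <- seq(bbox[2, 1], bbox[2, 2], length.out = resolution)
  zs <- seq(bbox[3, 1], bbox[3, 2], length.out = resolution)
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  mesh <- iso_from_grid(grid, f(grid), rep(resolution, 3L), 0, label = "source")
  if (mesh_n_components(mesh) != 1L)
    stop("resolution too small: lobes extracted as separate components")
  if (mesh_euler(mesh) != 2L)
    stop("resolution too small: extracted surface is not genus 0")
  attr(mesh, "shape") <- shape
  mesh
}

# Blend sharpness of the smooth-max lobe union (dimensionless); larger is
# closer to a hard union with a crease, smaller inflates the junction.
LOBE_BLEND_SHARPNESS <- 6

# Lobe geometry, jittered a few percent by the seed
liver_shape_params <- function(seed) {
  with_seed(seed, {
    jit <- function(x, frac = 0.04) x * (1 + stats::runif(length(x), -frac, frac))
    list(
      right_center = jit(c(-38, -8, 0), 0.06),
      right_axes   = jit(c(68, 72, 38)),
      left_center  = jit(c(52, 20, -4), 0.06),
      left_axes    = jit(c(48, 48, 30))
    )
  })
}

# save/restore .Random.seed so generators do not disturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_seed <- function(seed, code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Implicit function: positive inside, zero on the surface; smooth-max union
# of the two lobe ellipsoid functions
liver_implicit <- function(shape) {
  k <- LOBE_BLEND_SHARPNESS
  ell <- function(p, center, axes) {
    1 - ((p[, 1] - center[1]) / axes[1])^2 -
      ((p[, 2] - center[2]) / axes[2])^2 -
      ((p[, 3] - center[3]) / axes[3])^2
  }
  function(p) {
    p <- as.matrix(p)
    f1 <- ell(p, shape$right_center, shape$right_axes)
    f2 <- ell(p, shape$left_center, shape$left_axes)
    m <- pmax(f1, f2)
    m + log(exp(k * (f1 - m)) + exp(k * (f2 - m))) / k
  }
}

#' Occupancy field of the synthetic liver
#'
#' Squashes the liver implicit function through a logistic so values lie in
#' (0, 1) with 0.5 on the surface; used to exercise the generic iso-surface
#' extraction on a liver-shaped field.
#'
#' @inheritParams make_liver_mesh
#' @param sharpness Logistic steepness (1/implicit-unit).
#' @return An [occupancy_field()].
#' @export
liver_occupancy_field <- function(seed = 1L, resolution = 64L, sharpness = 8) {
  f <- liver_implicit(liver_shape_params(seed))
  occupancy_field(function(p) stats::plogis(sharpness * f(p)),
                  bbox = rbind(c(-115, 115), c(-90, 90), c(-55, 55)),
                  threshold = 0.5, grid_resolution = resolution)
}

#' Fiducial marker set
#'
#' Labelled 3D marker positions (mm). Fiducials are interior points — the
#' physical analogues are markers embedded in a gelatin phantom — and target
#' registration error is computed on them, never on surface vertices.
#'
#' @param ids Character or integer labels, unique.
#' @param positions Numeric `n x 3` matrix, mm.
#' @return A tibble of class `fiducial_set` with columns `id`, `x`, `y`, `z`.
#' @export
fiducial_set <- function(ids, positions) {
  positions <- as.matrix(positions)
  if (length(ids) != nrow(positions)) stop("one id per position required")
  if (anyDuplicated(ids)) stop("fiducial ids must be unique")
  if (length(ids) < 1L) stop("at least one fiducial is required")
  if (any(!is.finite(positions))) stop("fiducial positions must be finite")
  out <- tibble::tibble(id = as.character(ids),
                        x = positions[, 1], y = positions[, 2],
                        z = positions[, 3])
  class(out) <- c("fiducial_set", class(out))
  out
}

fiducial_matrix <- function(fids) {
  as.matrix(fids[, c("x", "y", "z")])
}

#' Sample interior fiducial markers
#'
#' Draws `n` approximately uniform points strictly inside a watertight mesh by
#' rejection sampling over the bounding box, keeping points whose generalized
#' winding number classifies them as interior and whose depth (distance to
#' the nearest surface vertex) exceeds `min_depth`.
#'
#' @param mesh A watertight `tri_mesh`.
#' @param n Number of markers (>= 1). The physical phantoms this emulates
#'   carry 53 or 176 markers.
#' @param seed Integer seed; deterministic for a fixed seed.
#' @param min_depth Minimum distance from the surface vertices, mm.
#' @return A [fiducial_set()] of `n` markers with ids `"f001"`, `"f002"`, ...
#' @export
sample_fiducials <- function(mesh, n, seed = 1L, min_depth = 2) {
  if (n < 1L) stop("`n` must be >= 1")
  if (!is_watertight(mesh))
    stop("mesh must be watertight: interior is undefined otherwise")
  bb <- mesh_bbox(mesh)
  pts <- with_seed(seed, {
    acc <- matrix(numeric(0), 0, 3)
    while (nrow(acc) < n) {
      m <- max(4L * n, 64L)
      cand <- cbind(stats::runif(m, bb[1, 1], bb[1, 2]),
                    stats::runif(m, bb[2, 1], bb[2, 2]),
                    stats::runif(m, bb[3, 1], bb[3, 2]))
      keep <- points_inside_mesh(mesh, cand)
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > 0) {
        d <- nearest_neighbours(cand, mesh$vertices)$dist
        cand <- cand[d > min_depth, , drop = FALSE]
      }
      acc <- rbind(acc, cand)
    }
    acc[seq_len(n), , drop = FALSE]
  })
  fiducial_set(sprintf("f%03d", seq_len(n)), pts)
}

#' Wedge deformation
#'
#' Analytic stand-in for placing a physical wedge under the phantom: a
#' C1-smooth vertical bump displacement applied to everything above the
#' wedge footprint,
#' `u(v) = height * max(0, 1 - (r/radius)^2)^2` along +z, where `r` is the
#' in-plane (x, y) distance of `v` from the wedge centre. The displacement is
#' zero outside the footprint and maximal (= `height`) at the centre.
#'
#' @param center Length-2 in-plane position of the wedge centre, mm.
#' @param radius Footprint radius, mm (> 0).
#' @param height Apex displacement, mm (>= 0).
#' @param lobe Which lobe the wedge sits under: `"left"`, `"right"` or
#'   `"both"` (metadata describing placement; the field itself is defined by
#'   `center`/`radius`).
#' @return A `wedge_deformation` object.
#' @export
wedge_deformation <- function(center, radius, height, lobe = "left") {
  if (length(center) != 2L || any(!is.finite(center)))
    stop("`center` must be a finite length-2 in-plane position")
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  if (!is.finite(height) || height < 0) stop("`height` must be >= 0")
  lobe <- match.arg(lobe, c("left", "right", "both"))
  structure(list(center = as.numeric(center), radius = radius,
                 height = height, lobe = lobe),
            class = "wedge_deformation")
}

# vertical displacement of the wedge field at in-plane radii r
wedge_profile <- function(wedge, r) {
  wedge$height * pmax(0, 1 - (r / wedge$radius)^2)^2
}

wedge_displacement <- function(wedge, points) {
  r <- sqrt((points[, 1] - wedge$center[1])^2 +
              (points[, 2] - wedge$center[2])^2)
  cbind(0, 0, wedge_profile(wedge, r))
}

#' Apply a wedge deformation to a mesh and its fiducials
#'
#' Displaces every vertex and fiducial along +z by the wedge bump field.
#' Topology (the face list) is unchanged. If the field is steep enough that
#' folding is possible (`height > radius`), the outputs carry a
#' `"deformation_warning"` attribute instead of being silently corrupted.
#'
#' @param mesh A `tri_mesh`.
#' @param fids A [fiducial_set()], or `NULL`.
#' @param wedge A [wedge_deformation()].
#' @return A list with elements `mesh` (deformed `tri_mesh`, label suffixed
#'   `"_deformed"`) and `fids` (displaced fiducials or `NULL`).
#' @export
apply_wedge <- function(mesh, fids, wedge) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(wedge, "wedge_deformation"))
  v <- mesh$vertices + wedge_displacement(wedge, mesh$vertices)
  out_mesh <- tri_mesh(v, mesh$faces, label = paste0(mesh$label, "_deformed"))
  out_fids <- NULL
  if (!is.null(fids)) {
    p <- fiducial_matrix(fids) + wedge_displacement(wedge, fiducial_matrix(fids))
    out_fids <- fiducial_set(fids$id, p)
  }
  # max |du_z/dr| of the bump is about 1.1 h / R at r = R/sqrt(3); a slope
  # beyond 1 means nearly vertical shearing where self-intersection is likely
  if (wedge$height > wedge$radius) {
    attr(out_mesh, "deformation_warning") <-
      "wedge slope exceeds 1: surface self-intersection possible"
  }
  list(mesh = out_mesh, fids = out_fids)
}

#' Generate a family of wedge-deformed phantoms
#'
#' Draws `n` wedge deformations with centre uniform over the mesh footprint
#' (restricted to the drawn lobe's half-plane), radius uniform in
#' [20, 60] mm, height uniform in [5, 25] mm and the lobe drawn at random
#' (`"both"` applies one wedge under each lobe), and applies each to the
#' input. Deterministic per seed.
#'
#' @param mesh Undeformed `tri_mesh`.
#' @param n Number of deformed copies (>= 1).
#' @param seed Integer seed.
#' @param fids Optional [fiducial_set()] deformed alongside each copy.
#' @return A list of `n` elements, each a list with `mesh`, `fids` (or
#'   `NULL`) and `wedges` (the wedge parameters used).
#' @export
generate_deformation_family <- function(mesh, n, seed = 1L, fids = NULL) {
  if (n < 1L) stop("`n` must be >= 1")
  bb <- mesh_bbox(mesh)
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lobe <- sample(c("left", "right", "both"), 1L)
      mk <- function(side) {
        xr <- if (side == "left") c(0, bb[1, 2]) else c(bb[1, 1], 0)
        wedge_deformation(
          center = c(stats::runif(1, xr[1], xr[2]),
                     stats::runif(1, bb[2, 1], bb[2, 2])),
          radius = stats::runif(1, 20, 60),
          height = stats::runif(1, 5, 25),
          lobe = side)
      }
      if (lobe == "both") list(mk("left"), mk("right")) else list(mk(lobe))
    })
  })
  lapply(seq_len(n), function(i) {
    m <- mesh; f <- fids
    for (w in draws[[i]]) {
      res <- apply_wedge(m, f, w)
      m <- res$mesh; f <- res$fids
    }
    m$label <- sprintf("%s_deformed_%02d", mesh$label, i)
    list(mesh = m, fids = f, wedges = draws[[i]])
  })
}

#' Split a family into train/validation/test partitions
#'
#' Deterministic index split in a given ratio (default 8:1:1, the customary
#' split for learning-based completion corpora), assigning the first block to
#' train, the next to validation, the rest to test.
#'
#' @param n Family size.
#' @param ratio Length-3 positive weights.
#' @return A list with integer index vectors `train`, `validation`, `test`.
#' @export
split_family <- function(n, ratio = c(8, 1, 1)) {
  stopifnot(length(ratio) == 3L, all(ratio > 0), n >= 1L)
  w <- ratio / sum(ratio)
  n_train <- as.integer(floor(n * w[1]))
  n_val <- as.integer(floor(n * w[2]))
  list(train = seq_len(n_train),
       validation = seq_len(n_val) + n_train,
       test = seq(n_train + n_val + 1L, length.out = n - n_train - n_val))
}
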