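#' Per-vertex nearest-vertex distance map
#'
#' For every vertex `p` of the generated target, the minimum Euclidean
#' distance to any vertex of the ground-truth target,
#' `d(p, G) = min_{g in G} ||p - g||`. Deliberately vertex-to-vertex (not
#' point-to-triangle): the quantity evaluated and visualized throughout the
#' pipeline. A point-to-surface variant is available via
#' [nearest_surface_distance()] for sensitivity checks only.
#'
#' @param gen Generated-target `tri_mesh` (or a `generated_target`).
#' @param gt Ground-truth target `tri_mesh`.
#' @return A `distance_map`: tibble with columns `vertex`, `x`, `y`, `z`,
#'   `distance` (mm), with attribute `summary` (mean, max, 95th percentile).
#' @export
nearest_vertex_distance <- function(gen, gt) {
  if (inherits(gen, "generated_target")) gen <- gen$mesh
  stopifnot(inherits(gen, "tri_mesh"), inherits(gt, "tri_mesh"))
  d <- nearest_neighbours(gen$vertices, gt$vertices)$dist
  out <- tibble::tibble(vertex = seq_len(nrow(gen$vertices)),
                        x = gen$vertices[, 1], y = gen$vertices[, 2],
                        z = gen$vertices[, 3], distance = d)
  class(out) <- c("distance_map", class(out))
  attr(out, "summary") <- c(mean = mean(d), max = max(d),
                            p95 = unname(stats::quantile(d, 0.95)))
  out
}

#' Point-to-triangle distance map (sensitivity variant)
#'
#' Distance from each generated vertex to the closest point on any
#' ground-truth triangle. Never feeds the headline outputs; provided to
#' check how much the vertex-to-vertex convention matters.
#'
#' @inheritParams nearest_vertex_distance
#' @return Numeric vector of distances, mm.
#' @export
nearest_surface_distance <- function(gen, gt) {
  if (inherits(gen, "generated_target")) gen <- gen$mesh
  p <- gen$vertices
  va <- gt$vertices[gt$faces[, 1], , drop = FALSE]
  vb <- gt$vertices[gt$faces[, 2], , drop = FALSE]
  vc <- gt$vertices[gt$faces[, 3], , drop = FALSE]
  vapply(seq_len(nrow(p)), function(i) {
    min(point_triangle_dist(p[i, ], va, vb, vc))
  }, numeric(1))
}

# vectorized point-to-triangle distance over all triangles (Eberly's
# projection onto the triangle's barycentric domain, clamped to edges)
point_triangle_dist <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  a11 <- rowSums(ab * ab); a12 <- rowSums(ab * ac); a22 <- rowSums(ac * ac)
  det <- pmax(a11 * a22 - a12^2, 1e-30)
  u <- (a22 * d1 - a12 * d2) / det
  v <- (a11 * d2 - a12 * d1) / det
  # clamp to the triangle by projecting onto edges where outside
  u <- pmax(u, 0); v <- pmax(v, 0)
  s <- u + v
  scale <- ifelse(s > 1, 1 / s, 1)
  u <- u * scale; v <- v * scale
  q <- a + u * ab + v * ac
  sqrt(rowSums(sweep(q, 2, p)^2))
}

#' @export
tidy.distance_map <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.distance_map <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(mean = s["mean"], max = s["max"], p95 = s["p95"],
                 n_vertices = nrow(x))
}

#' Target registration error
#'
#' Mean Euclidean distance between registered source fiducials and their
#' true target positions, `TRE = (1/N) sum_i ||x_i - x_i'||`, plus the
#' per-marker distances.
#'
#' @param registered_fids Registered source [fiducial_set()] (positions
#'   `x_i'`).
#' @param target_fids Target [fiducial_set()] (positions `x_i`); must carry
#'   the same ids.
#' @return A `tre_report`: list with `per_marker` (tibble `id`, `error`),
#'   `tre` (mean, mm) and `n`.
#' @export
tre <- function(registered_fids, target_fids) {
  if (!setequal(registered_fids$id, target_fids$id)) {
    bad <- c(setdiff(registered_fids$id, target_fids$id),
             setdiff(target_fids$id, registered_fids$id))
    stop("fiducial id sets differ: ", paste(bad, collapse = ", "))
  }
  tgt <- target_fids[match(registered_fids$id, target_fids$id), ]
  err <- sqrt(rowSums((fiducial_matrix(registered_fids) -
                         fiducial_matrix(tgt))^2))
  structure(list(per_marker = tibble::tibble(id = registered_fids$id,
                                             error = err),
                 tre = mean(err), n = length(err)),
            class = "tre_report")
}

#' @export
print.tre_report <- function(x, ...) {
  cat(sprintf("<tre_report: TRE %.3f mm over %d markers>\n", x$tre, x$n))
  invisible(x)
}

#' @export
tidy.tre_report <- function(x, ...) x$per_marker

#' @export
glance.tre_report <- function(x, ...) tibble::tibble(tre = x$tre, n = x$n)

#' Split fiducials into visible and invisible regions
#'
#' Markers within `threshold` of the partial-target centroid belong to the
#' visible region (the camera's field of view); the rest are invisible. A
#' marker exactly at the threshold is visible.
#'
#' @param target_fids Target [fiducial_set()].
#' @param partial A `partial_target` point cloud.
#' @param threshold Radius, mm (> 0); default 30.
#' @return A `region_split`: list with `threshold`, `centroid`,
#'   `visible_ids`, `invisible_ids`.
#' @export
split_visible <- function(target_fids, partial, threshold = 30) {
  if (threshold <= 0) stop("`threshold` must be > 0")
  ctr <- colMeans(point_matrix(partial))
  d <- sqrt(rowSums(sweep(fiducial_matrix(target_fids), 2, ctr)^2))
  structure(list(threshold = threshold, centroid = ctr,
                 visible_ids = target_fids$id[d <= threshold],
                 invisible_ids = target_fids$id[d > threshold]),
            class = "region_split")
}

#' @export
print.region_split <- function(x, ...) {
  cat(sprintf("<region_split at %g mm: %d visible, %d invisible>\n",
              x$threshold, length(x$visible_ids), length(x$invisible_ids)))
  invisible(x)
}

# TRE restricted to a subset of marker ids; NA when the subset is empty
# (an empty region is reported as missing, never as zero)
tre_subset <- function(registered_fids, target_fids, ids) {
  if (length(ids) == 0L) return(NA_real_)
  tre(registered_fids[registered_fids$id %in% ids, ],
      target_fids[target_fids$id %in% ids, ])$tre
}

#' TRE-versus-coverage curve
#'
#' Pairs each coverage fraction with its registration TRE and marks the
#' best (minimal-TRE) point, ties broken toward lower coverage.
#'
#' @param coverages Strictly increasing coverage fractions.
#' @param tres One TRE (mm) per coverage.
#' @return A `coverage_curve` tibble with columns `coverage`, `tre`, `best`
#'   (logical, exactly one `TRUE`).
#' @export
coverage_curve <- function(coverages, tres) {
  if (length(coverages) != length(tres))
    stop("one TRE per coverage level is required")
  if (any(diff(coverages) <= 0))
    stop("coverage fractions must be strictly increasing")
  best <- which.min(tres)  # which.min returns the first minimum
  out <- tibble::tibble(coverage = coverages, tre = tres,
                        best = seq_along(tres) == best)
  class(out) <- c("coverage_curve", class(out))
  out
}

#' @export
glance.coverage_curve <- function(x, ...) {
  b <- x[x$best, ]
  tibble::tibble(best_coverage = b$coverage, best_tre = b$tre,
                 full_tre = x$tre[nrow(x)], n_levels = nrow(x))
}

#' Threshold sensitivity sweep
#'
#' Recomputes the visible/invisible TRE at the best-coverage and at the
#' full-coverage registration for a list of region thresholds. Empty regions
#' are reported with `n = 0` and a missing TRE.
#'
#' @param target_fids Target [fiducial_set()].
#' @param partial The `partial_target` defining the centroid.
#' @param best_fids Registered source fiducials at best coverage.
#' @param full_fids Registered source fiducials at full coverage.
#' @param thresholds Positive, sorted radii, mm; default
#'   `c(10, 20, 30, 40, 50, 60)` with 30 the headline value.
#' @return Tibble with columns `threshold`, `region` (visible/invisible),
#'   `n`, `tre_best`, `tre_full`.
#' @export
sensitivity_sweep <- function(target_fids, partial, best_fids, full_fids,
                              thresholds = c(10, 20, 30, 40, 50, 60)) {
  if (any(thresholds <= 0) || is.unsorted(thresholds))
    stop("`thresholds` must be positive and sorted")
  purrr::map_dfr(thresholds, function(th) {
    sp <- split_visible(target_fids, partial, th)
    tibble::tibble(
      threshold = th,
      region = c("visible", "invisible"),
      n = c(length(sp$visible_ids), length(sp$invisible_ids)),
      tre_best = c(tre_subset(best_fids, target_fids, sp$visible_ids),
                   tre_subset(best_fids, target_fids, sp$invisible_ids)),
      tre_full = c(tre_subset(full_fids, target_fids, sp$visible_ids),
                   tre_subset(full_fids, target_fids, sp$invisible_ids)))
  })
}

#' Summarize an experiment across viewpoints
#'
#' Mean and population standard deviation (divide by n, the convention used
#' throughout the package's reports) across viewpoints of the
#' visible/invisible TRE at best and full coverage, per phantom and
#' registration mode.
#'
#' @param results Tibble with one row per (phantom, viewpoint, mode) and
#'   numeric columns `visible_best`, `visible_full`, `invisible_best`,
#'   `invisible_full`.
#' @return Tibble with one row per phantom x mode: for each of the four
#'   quantities, columns `<name>_mean` and `<name>_sd`.
#' @export
summarize_experiment <- function(results) {
  stopifnot(all(c("phantom", "viewpoint", "mode", "visible_best",
                  "visible_full", "invisible_best", "invisible_full")
                %in% names(results)))
  sd_pop <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  results |>
    dplyr::group_by(.data$phantom, .data$mode) |>
    dplyr::summarise(dplyr::across(
      c("visible_best", "visible_full", "invisible_best", "invisible_full"),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd_pop(.x))),
      .groups = "drop")
}
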