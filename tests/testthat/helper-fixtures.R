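# Shared fixtures: tiny hand-built meshes, a cached low-resolution phantom,
# and analytic fields. All deterministic.

# unit cube [0,1]^3: 8 vertices, 12 outward-oriented triangles, watertight
unit_cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom (-z)
             c(5, 6, 7), c(5, 7, 8),   # top (+z)
             c(1, 2, 6), c(1, 6, 5),   # front (-y)
             c(3, 4, 8), c(3, 8, 7),   # back (+y)
             c(1, 5, 8), c(1, 8, 4),   # left (-x)
             c(2, 3, 7), c(2, 7, 6))   # right (+x)
  tri_mesh(v, f, label = "cube")
}

# unit right tetrahedron, volume 1/6, outward-oriented
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f, label = "tetra")
}

# low-resolution phantom, built once per test run
small_liver <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_liver_mesh(seed = 1L, resolution = 32L)
    cache
  }
})

# smooth sphere occupancy field: value 0.5 exactly at r = radius
sphere_field <- function(radius = 50, half_width = 75, resolution = 64L,
                         softness = 4) {
  occupancy_field(
    function(p) stats::plogis((radius - sqrt(rowSums(p^2))) / softness),
    bbox = rbind(c(-1, 1), c(-1, 1), c(-1, 1)) * half_width,
    threshold = 0.5, grid_resolution = resolution)
}

# ---- independent oracles (deliberately naive implementations) ----

# brute-force nearest neighbour by double loop
oracle_nn <- function(query, ref) {
  q <- as.matrix(query); r <- as.matrix(ref)
  idx <- integer(nrow(q)); dist <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    best <- Inf; bj <- 0L
    for (j in seq_len(nrow(r))) {
      d <- sum((q[i, ] - r[j, ])^2)
      if (d < best) { best <- d; bj <- j }
    }
    idx[i] <- bj; dist[i] <- sqrt(best)
  }
  list(idx = idx, dist = dist)
}

# point-in-mesh by ray parity: count triangle crossings of a +x ray
# (Moller-Trumbore), odd count = inside
oracle_inside <- function(mesh, points) {
  p <- as.matrix(points)
  va <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  vb <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  vc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  dir <- c(1, 0.0000123, 0.0000457)  # slightly tilted to dodge edge hits
  apply(p, 1, function(o) {
    hits <- 0L
    for (k in seq_len(nrow(va))) {
      e1 <- vb[k, ] - va[k, ]; e2 <- vc[k, ] - va[k, ]
      h <- c(dir[2] * e2[3] - dir[3] * e2[2],
             dir[3] * e2[1] - dir[1] * e2[3],
             dir[1] * e2[2] - dir[2] * e2[1])
      a <- sum(e1 * h)
      if (abs(a) < 1e-12) next
      s <- o - va[k, ]
      u <- sum(s * h) / a
      if (u < 0 || u > 1) next
      q <- c(s[2] * e1[3] - s[3] * e1[2],
             s[3] * e1[1] - s[1] * e1[3],
             s[1] * e1[2] - s[2] * e1[1])
      v <- sum(dir * q) / a
      if (v < 0 || u + v > 1) next
      t <- sum(e2 * q) / a
      if (t > 1e-12) hits <- hits + 1L
    }
    hits %% 2L == 1L
  })
}

# multi-source BFS distance over a mesh's vertex adjacency, hand-coded queue
oracle_bfs_distance <- function(mesh, seeds) {
  n <- nrow(mesh$vertices)
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- rep(Inf, n)
  d[seeds] <- 0
  queue <- as.integer(seeds)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; queue <- c(queue, w) }
    }
  }
  d
}

# angle in degrees between two rotation matrices
rotation_error_deg <- function(Ra, Rb) {
  R <- Ra %*% t(Rb)
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
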