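# random "meshes" (vertex clouds with a token face) for exact-oracle checks
cloud_mesh <- function(n, seed) {
  set.seed(seed)
  tri_mesh(matrix(rnorm(3 * n, sd = 40), ncol = 3), rbind(c(1L, 2L, 3L)))
}

test_that("vertex distance map equals the double-loop definition", {
  gen <- cloud_mesh(120, 1)
  gt <- cloud_mesh(150, 2)
  dm <- nearest_vertex_distance(gen, gt)
  want <- oracle_nn(gen$vertices, gt$vertices)$dist
  expect_equal(dm$distance, want, tolerance = 1e-12)
  expect_identical(nrow(dm), 120L)
  s <- attr(dm, "summary")
  expect_equal(unname(s["mean"]), mean(want), tolerance = 1e-12)
  expect_equal(unname(s["max"]), max(want), tolerance = 1e-12)
})

test_that("surface distance is never farther than vertex distance", {
  gt <- small_liver()
  set.seed(31)
  gen <- tri_mesh(gt$vertices + matrix(rnorm(length(gt$vertices), sd = 2),
                                       ncol = 3), gt$faces)
  sub <- tri_mesh(gen$vertices[1:200, , drop = FALSE], rbind(c(1L, 2L, 3L)))
  dv <- nearest_vertex_distance(sub, gt)$distance
  ds <- nearest_surface_distance(sub, gt)
  expect_true(all(ds <= dv + 1e-9))
})

test_that("TRE equals the brute-force mean of marker distances", {
  set.seed(5)
  a <- matrix(rnorm(30, sd = 20), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 3), ncol = 3)
  fa <- fiducial_set(paste0("f", 1:10), a)
  fb <- fiducial_set(paste0("f", 1:10), b)
  rep_ <- tre(fa, fb)
  want <- mean(sqrt(rowSums((a - b)^2)))
  expect_equal(rep_$tre, want, tolerance = 1e-12)
  expect_identical(rep_$n, 10L)
  # id matching is by label, not by row order
  shuffled <- fb[sample(10), ]
  class(shuffled) <- class(fb)
  expect_equal(tre(fa, shuffled)$tre, want, tolerance = 1e-12)
  expect_error(tre(fa, fiducial_set(paste0("g", 1:10), b)), "differ")
})

test_that("region split equals a brute-force distance filter", {
  liver <- small_liver()
  vp <- make_viewpoints(liver)$vp2
  partial <- simulate_partial_target(liver, vp, n_anterior = 500L, k = 150L,
                                     seed = 6L)
  fids <- sample_fiducials(liver, 40L, seed = 3L)
  sp <- split_visible(fids, partial, threshold = 30)
  ctr <- colMeans(as.matrix(partial[, c("x", "y", "z")]))
  d <- sqrt(rowSums(sweep(as.matrix(fids[, c("x", "y", "z")]), 2, ctr)^2))
  expect_identical(sp$visible_ids, fids$id[d <= 30])
  expect_identical(sp$invisible_ids, fids$id[d > 30])
  expect_error(split_visible(fids, partial, threshold = 0), "threshold")
})

test_that("an empty region reports a missing TRE, never zero", {
  a <- fiducial_set(c("a", "b"), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_identical(liverreg:::tre_subset(a, a, character(0)), NA_real_)
  expect_equal(liverreg:::tre_subset(a, a, c("a")), 0)
})

test_that("coverage curve flags the first minimum, ties to lower coverage", {
  cc <- coverage_curve(c(0.2, 0.4, 0.6, 0.8, 1.0), c(5, 3, 4, 3, 6))
  expect_identical(which(cc$best), 2L)
  expect_identical(sum(cc$best), 1L)
  gl <- glance(cc)
  expect_equal(gl$best_coverage, 0.4)
  expect_equal(gl$full_tre, 6)
  expect_error(coverage_curve(c(0.2, 0.2), c(1, 2)), "increasing")
  expect_error(coverage_curve(c(0.2, 0.4), c(1, 2, 3)), "one TRE per")
})

test_that("sensitivity sweep partitions the markers at every threshold", {
  liver <- small_liver()
  vp <- make_viewpoints(liver)$vp1
  partial <- simulate_partial_target(liver, vp, n_anterior = 500L, k = 150L,
                                     seed = 2L)
  fids <- sample_fiducials(liver, 30L, seed = 9L)
  moved <- fiducial_set(fids$id, as.matrix(fids[, c("x", "y", "z")]) + 2)
  sw <- sensitivity_sweep(fids, partial, moved, moved, thresholds = c(20, 30, 50))
  expect_identical(nrow(sw), 6L)  # 3 thresholds x 2 regions
  sums <- tapply(sw$n, sw$threshold, sum)
  expect_true(all(sums == 30L))
  expect_true(all(is.na(sw$tre_best) == (sw$n == 0)))
  expect_error(sensitivity_sweep(fids, partial, moved, moved, c(30, 10)),
               "sorted")
})

test_that("experiment summary computes means and population SDs", {
  results <- tibble::tibble(
    phantom = 1L, viewpoint = c("vp1", "vp2", "vp3"), mode = "rigid",
    visible_best = c(1, 2, 3), visible_full = c(2, 2, 2),
    invisible_best = c(4, NA, 6), invisible_full = c(5, 7, 9))
  sm <- summarize_experiment(results)
  expect_identical(nrow(sm), 1L)
  expect_equal(sm$visible_best_mean, 2)
  expect_equal(sm$visible_best_sd, sqrt(2 / 3))  # population, not sample, SD
  expect_equal(sm$visible_full_sd, 0)
  expect_equal(sm$invisible_best_mean, 5)        # NA dropped
  expect_equal(sm$invisible_best_sd, 1)
})
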