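# shared scene: one deformed phantom, one viewpoint, one partial target
completion_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      source_mesh <- small_liver()
      wedge <- wedge_deformation(center = c(52, 20), radius = 45, height = 15,
                                 lobe = "left")
      gt <- apply_wedge(source_mesh, NULL, wedge)$mesh
      vp <- make_viewpoints(gt)$vp4
      partial <- simulate_partial_target(gt, vp, n_anterior = 600L, k = 200L,
                                         seed = 11L)
      cache <<- list(source = source_mesh, gt = gt, partial = partial)
    }
    cache
  }
})

test_that("oracle completion returns the ground truth verbatim", {
  sc <- completion_scene()
  gen <- complete_oracle(sc$partial, sc$gt)
  expect_s3_class(gen, "generated_target")
  expect_identical(gen$method, "oracle")
  expect_identical(gen$mesh$vertices, sc$gt$vertices)
  expect_identical(gen$mesh$faces, sc$gt$faces)
})

test_that("prior completion aligns the source near the visible region", {
  sc <- completion_scene()
  gen <- complete_prior(sc$partial, sc$source, seed = 3L)
  expect_identical(gen$method, "prior")
  # same topology as the source: a rigidly moved copy
  expect_identical(gen$mesh$faces, sc$source$faces)
  # the aligned prior must hug the observed patch (which the wedge barely
  # moves at its rim) far better than it matches the full deformed surface
  pm <- as.matrix(sc$partial[, c("x", "y", "z")])
  d_patch <- mean(liverreg:::nearest_neighbours(pm, gen$mesh$vertices)$dist)
  expect_lt(d_patch, 8)  # well under the 15 mm deformation it cannot explain
})

test_that("undeformed ground truth makes the prior an exact completion", {
  liver <- small_liver()
  vp <- make_viewpoints(liver)$vp4
  partial <- simulate_partial_target(liver, vp, n_anterior = 600L, k = 200L,
                                     seed = 2L)
  gen <- complete_prior(partial, liver, seed = 1L)
  dm <- nearest_vertex_distance(gen$mesh, liver)
  expect_lt(mean(dm$distance), 0.5)  # source == gt, so alignment ~ identity
})

test_that("error-model parameters are validated", {
  expect_error(error_model_params(length_scale = 0), "length_scale")
  expect_error(error_model_params(noise_scale = -1), "noise_scale")
  p <- error_model_params(40, 4, seed = 2L)
  expect_s3_class(p, "error_model_params")
})

test_that("error-model completion is faithful near the view, degraded far away", {
  sc <- completion_scene()
  prior <- complete_prior(sc$partial, sc$source, seed = 3L)
  gen <- complete_with_error_model(sc$partial, sc$gt, sc$source,
                                   error_model_params(40, 4, seed = 5L),
                                   prior = prior)
  expect_identical(gen$method, "error_model")
  expect_identical(gen$mesh$faces, sc$gt$faces)  # topology preserved
  err <- sqrt(rowSums((gen$mesh$vertices - sc$gt$vertices)^2))
  D <- gen$params$D
  expect_true(all(is.finite(D)))
  # weights decay exponentially with geodesic distance
  expect_equal(gen$params$w, exp(-D / 40), tolerance = 1e-12)
  # near the view (seed set) the output is the ground truth
  expect_lt(mean(err[D < 1e-9]), 1e-6)
  # far from the view the error is materially larger
  far <- D > stats::quantile(D, 0.8)
  expect_gt(mean(err[far]), 5 * mean(err[D < 1e-9] + 1e-9))
  expect_gt(mean(err[far]), mean(err[D < stats::quantile(D, 0.2)]))
})

test_that("with no noise the completion interpolates gt and prior exactly", {
  sc <- completion_scene()
  prior <- complete_prior(sc$partial, sc$source, seed = 3L)
  gen <- complete_with_error_model(sc$partial, sc$gt, sc$source,
                                   error_model_params(40, 0, seed = 1L),
                                   prior = prior)
  w <- gen$params$w
  want <- w * sc$gt$vertices + (1 - w) * prior$mesh$vertices
  expect_equal(gen$mesh$vertices, want, tolerance = 1e-12)
})

test_that("completion error decays with the length scale", {
  sc <- completion_scene()
  prior <- complete_prior(sc$partial, sc$source, seed = 3L)
  gens <- lapply(c(20, 80), function(l) {
    complete_with_error_model(sc$partial, sc$gt, sc$source,
                              error_model_params(l, 0, seed = 1L),
                              prior = prior)
  })
  errs <- vapply(gens, function(g) {
    mean(sqrt(rowSums((g$mesh$vertices - sc$gt$vertices)^2)))
  }, numeric(1))
  expect_lt(errs[2], errs[1])  # longer length scale = more faithful surface
})

test_that("geodesic distances agree with an all-pairs igraph oracle", {
  cube <- unit_cube_mesh()
  seeds <- c(1L, 7L)
  got <- liverreg:::geodesic_to_set(cube, seeds)
  g <- liverreg:::mesh_graph(cube, weighted = TRUE)
  full <- igraph::distances(g, v = seeds)
  expect_equal(got, apply(full, 2, min), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(got[seeds], c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
})
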