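test_that("liver phantom is a closed, liver-scaled, single surface", {
  liver <- small_liver()
  expect_true(is_watertight(liver))
  expect_identical(mesh_euler(liver), 2L)
  expect_identical(liver$label, "source")
  bb <- liverreg:::mesh_bbox(liver)
  ext <- bb[, 2] - bb[, 1]
  expect_true(ext[1] > 160 && ext[1] < 240)  # ~200 mm wide
  expect_true(ext[2] > 110 && ext[2] < 180)
  expect_true(ext[3] > 55 && ext[3] < 110)
  vol_ml <- liverreg:::mesh_signed_volume(liver) / 1000
  expect_true(vol_ml > 700 && vol_ml < 1600)  # adult liver scale
})

test_that("phantom generation is deterministic per seed and varies across seeds", {
  a <- make_liver_mesh(seed = 3L, resolution = 32L)
  b <- make_liver_mesh(seed = 3L, resolution = 32L)
  c_ <- make_liver_mesh(seed = 4L, resolution = 32L)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_false(isTRUE(all.equal(a$vertices, c_$vertices)))
  expect_error(make_liver_mesh(resolution = 16L), ">= 32")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(liverreg:::with_seed(5, stats::runif(10)))
  expect_identical(.Random.seed, before)
})

test_that("fiducials are interior, deep enough, and deterministic", {
  liver <- small_liver()
  fids <- sample_fiducials(liver, 53L, seed = 2L, min_depth = 2)
  expect_s3_class(fids, "fiducial_set")
  expect_identical(nrow(fids), 53L)
  expect_identical(fids$id, sprintf("f%03d", 1:53))
  pm <- as.matrix(fids[, c("x", "y", "z")])
  expect_true(all(points_inside_mesh(liver, pm)))
  d <- liverreg:::nearest_neighbours(pm, liver$vertices)$dist
  expect_true(all(d > 2))
  again <- sample_fiducials(liver, 53L, seed = 2L, min_depth = 2)
  expect_identical(fids, again)
})

test_that("wedge bump is zero outside its footprint and maximal at centre", {
  w <- wedge_deformation(center = c(0, 0), radius = 40, height = 15)
  expect_equal(liverreg:::wedge_profile(w, 0), 15)
  expect_equal(liverreg:::wedge_profile(w, 40), 0)
  expect_equal(liverreg:::wedge_profile(w, 100), 0)
  r <- seq(0, 40, by = 1)
  expect_true(all(diff(liverreg:::wedge_profile(w, r)) <= 0))  # monotone decay
  expect_error(wedge_deformation(c(0, 0), radius = -1, height = 5), "radius")
  expect_error(wedge_deformation(c(0, 0), radius = 10, height = -5), "height")
})

test_that("apply_wedge displaces along +z only and preserves topology", {
  liver <- small_liver()
  fids <- sample_fiducials(liver, 5L, seed = 1L)
  w <- wedge_deformation(center = c(-38, -8), radius = 50, height = 15,
                         lobe = "right")
  out <- apply_wedge(liver, fids, w)
  expect_identical(out$mesh$faces, liver$faces)
  du <- out$mesh$vertices - liver$vertices
  expect_true(all(du[, 1:2] == 0))
  expect_true(all(du[, 3] >= 0))
  expect_true(max(du[, 3]) <= 15)
  # fiducials move by the same analytic field
  fm <- as.matrix(fids[, c("x", "y", "z")])
  r <- sqrt((fm[, 1] + 38)^2 + (fm[, 2] + 8)^2)
  expect_equal(out$fids$z - fids$z, liverreg:::wedge_profile(w, r))
  # steep wedges are flagged
  steep <- apply_wedge(liver, NULL, wedge_deformation(c(0, 0), 10, 20))
  expect_match(attr(steep$mesh, "deformation_warning"), "slope")
})

test_that("deformation family is deterministic with in-range parameters", {
  liver <- small_liver()
  fam <- generate_deformation_family(liver, 4L, seed = 7L)
  expect_length(fam, 4L)
  for (f in fam) {
    for (w in f$wedges) {
      expect_true(w$radius >= 20 && w$radius <= 60)
      expect_true(w$height >= 5 && w$height <= 25)
      expect_true(w$lobe %in% c("left", "right", "both"))
    }
  }
  fam2 <- generate_deformation_family(liver, 4L, seed = 7L)
  expect_identical(fam[[2]]$mesh$vertices, fam2[[2]]$mesh$vertices)
})

test_that("family split is 8:1:1 and partitions the indices", {
  sp <- split_family(4969L)
  expect_identical(lengths(sp), c(train = 3975L, validation = 496L, test = 498L))
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, 1:4969)
})
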