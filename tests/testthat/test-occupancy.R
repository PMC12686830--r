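test_that("occupancy_field validates its arguments", {
  f <- function(p) rep(0.5, nrow(p))
  bb <- rbind(c(-1, 1), c(-1, 1), c(-1, 1))
  expect_error(occupancy_field("nope", bb), "is.function")
  expect_error(occupancy_field(f, bb[1:2, ]), "3 x 2")
  expect_error(occupancy_field(f, bb, threshold = 0), "threshold")
  expect_error(occupancy_field(f, bb, grid_resolution = 8), ">= 16")
})

test_that("sphere iso-surface is watertight with vertices on the sphere", {
  field <- sphere_field(radius = 30, half_width = 50, resolution = 32)
  mesh <- extract_mesh_from_occupancy(field)
  expect_true(is_watertight(mesh))
  expect_identical(mesh_euler(mesh), 2L)
  radii <- sqrt(rowSums(mesh$vertices^2))
  cell <- 100 / 31
  expect_lt(max(abs(radii - 30)), 2 * cell)
  # enclosed volume approaches 4/3 pi r^3 (within a coarse-grid tolerance)
  vol <- liverreg:::mesh_signed_volume(mesh)
  expect_equal(vol, 4 / 3 * pi * 30^3, tolerance = 0.05)
})

test_that("iso-surface extraction refines toward the analytic volume", {
  true_vol <- 4 / 3 * pi * 30^3
  errs <- vapply(c(24L, 48L), function(res) {
    m <- extract_mesh_from_occupancy(
      sphere_field(radius = 30, half_width = 50, resolution = res))
    abs(liverreg:::mesh_signed_volume(m) - true_vol)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("iso-surface agrees with an independent marching-cubes program", {
  # scikit-image's marching_cubes as an external oracle on the same grid
  res <- 24L
  field <- sphere_field(radius = 30, half_width = 50, resolution = res)
  mesh <- extract_mesh_from_occupancy(field)
  script <- sprintf(paste0(
    "import numpy as np\n",
    "from skimage.measure import marching_cubes\n",
    "ax = np.linspace(-50, 50, %d)\n",
    "x, y, z = np.meshgrid(ax, ax, ax, indexing='ij')\n",
    "r = np.sqrt(x**2 + y**2 + z**2)\n",
    "vol = 1.0 / (1.0 + np.exp(-(30.0 - r) / 4.0))\n",
    "verts, faces, _, _ = marching_cubes(vol, level=0.5,\n",
    "    spacing=(100.0/%d, 100.0/%d, 100.0/%d))\n",
    "verts = verts - 50.0\n",
    "rad = np.sqrt((verts**2).sum(axis=1))\n",
    "print(rad.mean(), rad.max(), rad.min())\n"), res, res - 1, res - 1, res - 1)
  out <- suppressWarnings(system2("python3", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  ref <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  radii <- sqrt(rowSums(mesh$vertices^2))
  # same field, same grid: radius statistics must agree to sub-cell accuracy
  cell <- 100 / (res - 1)
  expect_lt(abs(mean(radii) - ref[1]), 0.25 * cell)
  expect_lt(abs(max(radii) - ref[2]), 0.5 * cell)
  expect_lt(abs(min(radii) - ref[3]), 0.5 * cell)
})

test_that("extraction refuses empty or boundary-touching surfaces", {
  bb <- rbind(c(-1, 1), c(-1, 1), c(-1, 1))
  empty <- occupancy_field(function(p) rep(0.1, nrow(p)), bb,
                           threshold = 0.5, grid_resolution = 16)
  expect_error(extract_mesh_from_occupancy(empty), "empty")
  full <- occupancy_field(function(p) rep(0.9, nrow(p)), bb,
                          threshold = 0.5, grid_resolution = 16)
  expect_error(extract_mesh_from_occupancy(full), "boundary")
})

test_that("a lower threshold encloses more volume on a radial ramp", {
  ramp <- occupancy_field(
    function(p) pmin(1, pmax(0, 1 - sqrt(rowSums(p^2)) / 60)),
    bbox = rbind(c(-70, 70), c(-70, 70), c(-70, 70)),
    threshold = 0.5, grid_resolution = 48)
  v04 <- occupancy_volume(ramp, threshold = 0.4)
  v05 <- occupancy_volume(ramp, threshold = 0.5)
  expect_gt(v04, v05)
  # ramp superlevel set at c is the ball of radius 60 (1 - c)
  expect_equal(v04, 4 / 3 * pi * (60 * 0.6)^3, tolerance = 0.05)
  expect_equal(v05, 4 / 3 * pi * (60 * 0.5)^3, tolerance = 0.05)
})

test_that("iso-surfacing the same field twice is bit-identical", {
  f <- sphere_field(radius = 30, half_width = 50, resolution = 24)
  m1 <- extract_mesh_from_occupancy(f)
  m2 <- extract_mesh_from_occupancy(f)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})
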