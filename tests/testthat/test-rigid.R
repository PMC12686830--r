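test_that("rigid_transform algebra: apply, invert, compose", {
  tr <- rigid_transform(liverreg:::rot_z(0.3), c(5, -2, 1))
  p <- matrix(rnorm(30), ncol = 3)
  q <- transform_points(tr, p)
  expect_equal(transform_points(invert_transform(tr), q), p,
               tolerance = 1e-12, ignore_attr = TRUE)
  tr2 <- rigid_transform(liverreg:::rot_x(-0.7), c(0, 3, 3))
  both <- compose_transforms(tr2, tr)
  expect_equal(transform_points(both, p),
               transform_points(tr2, transform_points(tr, p)),
               tolerance = 1e-12)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "orthonormal")
})

test_that("kabsch recovers an exact correspondence-based alignment", {
  set.seed(21)
  p <- matrix(rnorm(3 * 50, sd = 30), ncol = 3)
  true <- rigid_transform(liverreg:::compose_euler_xyz(c(0.4, -0.2, 1.1)),
                          c(12, -40, 7))
  q <- transform_points(true, p)
  est <- kabsch(p, q)
  # 1e-5 degrees is the acos() conditioning floor near a perfect recovery
  expect_lt(rotation_error_deg(est$rotation, true$rotation), 1e-5)
  expect_lt(max(abs(est$translation - true$translation)), 1e-9)
  expect_equal(det(est$rotation), 1, tolerance = 1e-12)
  # reflection correction: det stays +1 even for noisy, near-planar data
  flat <- cbind(p[, 1:2], rnorm(50, sd = 1e-3))
  est2 <- kabsch(flat, transform_points(true, flat))
  expect_equal(det(est2$rotation), 1, tolerance = 1e-9)
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(kabsch(line, line), "collinear")
})

test_that("icp on an already-aligned cloud stops immediately at identity", {
  cloud <- small_liver()$vertices
  fit <- icp(cloud, cloud)
  expect_identical(fit$iterations, 1L)
  expect_true(fit$converged)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_lt(rotation_error_deg(fit$transform$rotation, diag(3)), 1e-9)
})

test_that("icp RMSE trace never increases", {
  cloud <- liverreg:::budget_sample(small_liver()$vertices, 800L, 1)
  pose <- rigid_transform(liverreg:::compose_euler_xyz(c(0.3, -0.2, 0.25)),
                          c(15, -10, 20))
  fit <- icp(transform_points(pose, cloud), cloud)
  expect_true(all(diff(fit$rmse_trace) <= 1e-9))
})

test_that("random restarts stay in the documented angle range", {
  for (s in 1:20) {
    R <- random_rotation(s)$rotation
    ang <- liverreg:::euler_xyz(R)
    expect_true(all(abs(ang) <= pi / 2 + 1e-9))
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(random_rotation(5)$rotation, random_rotation(5)$rotation)
})

test_that("multistart_icp is deterministic and reports every restart", {
  cloud <- liverreg:::budget_sample(small_liver()$vertices, 500L, 2)
  pose <- rigid_transform(liverreg:::compose_euler_xyz(c(1.2, -0.9, 1.0)))
  moved <- transform_points(pose, cloud)
  fit <- multistart_icp(moved, cloud, n_restarts = 4L, seed = 9L)
  expect_length(attr(fit, "all_rmse"), 5L)  # identity + 4 restarts
  expect_true(fit$restart_index %in% 0:4)
  expect_equal(fit$rmse, min(attr(fit, "all_rmse")))
  fit2 <- multistart_icp(moved, cloud, n_restarts = 4L, seed = 9L)
  expect_identical(fit$transform, fit2$transform)
  expect_error(multistart_icp(moved, cloud, n_restarts = 0L), "n_restarts")
})

test_that("tidy and glance expose pose parameters and fit quality", {
  fit <- icp(small_liver()$vertices, small_liver()$vertices)
  td <- tidy(fit)
  expect_identical(td$term, c("euler_x", "euler_y", "euler_z",
                              "t_x", "t_y", "t_z"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$iterations, 1L)
})
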