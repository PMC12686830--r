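# deterministic sphere-with-bump pair: the truth is a smooth 12 mm bump
bump_pair <- function(n = 300L, radius = 50, height = 12) {
  set.seed(4242)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * radius
  bump <- height * exp(-(u[, 1]^2 + u[, 2]^2) / (2 * 15^2)) * (u[, 3] > 0)
  list(src = u, tgt = u + cbind(0, 0, bump))
}

test_that("cpd_nonrigid validates its inputs", {
  p <- bump_pair(20L)
  expect_error(cpd_nonrigid(p$src[1:5, ], p$tgt), "at least 10")
  expect_error(cpd_nonrigid(p$src, p$tgt, beta = 0), "beta")
  expect_error(cpd_nonrigid(p$src, p$tgt, lambda = -1), "lambda")
  expect_error(cpd_nonrigid(p$src, p$tgt, w_outlier = 1), "w_outlier")
})

test_that("identical clouds produce a near-zero displacement field", {
  p <- bump_pair(100L)
  fit <- cpd_nonrigid(p$src, p$src)
  expect_lt(max(abs(fit$displacements)), 1e-3)
})

test_that("cpd recovers a smooth known deformation", {
  p <- bump_pair(300L)
  # kernel width matched to the 15 mm correlation length of the bump
  fit <- cpd_nonrigid(p$src, p$tgt, beta = 15)
  expect_true(fit$converged)
  resid <- sqrt(rowSums((p$src + fit$displacements - p$tgt)^2))
  expect_lt(mean(resid), 0.25)            # mm, against a 12 mm deformation
  expect_gt(max(sqrt(rowSums(fit$displacements^2))), 9)  # bump mostly recovered
})

test_that("registration is invariant to the measurement unit", {
  p <- bump_pair(150L)
  fit_mm <- cpd_nonrigid(p$src, p$tgt)
  fit_um <- cpd_nonrigid(p$src * 1000, p$tgt * 1000,
                         beta = fit_mm$beta * 1000)
  expect_equal(fit_um$displacements / 1000, fit_mm$displacements,
               tolerance = 1e-6)
})

test_that("a pure shift is recovered by the translation, not the kernel", {
  p <- bump_pair(200L)
  shift <- c(8, -5, 6)
  fit <- cpd_nonrigid(p$src, sweep(p$src, 2, shift, "+"))
  # mean displacement within 5% of the shift in the shift direction
  expect_equal(colMeans(fit$displacements), shift,
               tolerance = 0.05, ignore_attr = TRUE)
  # the field is constant everywhere: fiducials far inside the cloud move
  # by the same shift within 1%
  set.seed(77)
  interior <- matrix(runif(3 * 40, -25, 25), ncol = 3)
  fids <- fiducial_set(sprintf("i%02d", 1:40), interior)
  moved <- apply_displacement_to_fiducials(fids, fit)
  disp <- as.matrix(moved[, c("x", "y", "z")]) - interior
  err <- sqrt(rowSums(sweep(disp, 2, shift)^2))
  expect_lt(max(err), 0.01 * sqrt(sum(shift^2)))
})

test_that("very large lambda drives the field toward a constant", {
  p <- bump_pair(200L)
  fit <- cpd_nonrigid(p$src, p$tgt, lambda = 1e10)
  dev <- sweep(fit$displacements, 2, colMeans(fit$displacements))
  expect_lt(max(abs(dev)), 1e-4)
})

test_that("sigma2 trace decreases overall as EM fits the target", {
  p <- bump_pair(200L)
  fit <- cpd_nonrigid(p$src, p$tgt)
  tr <- fit$sigma2_trace
  expect_gt(length(tr), 1L)
  expect_lt(tr[length(tr)], tr[1])
})

test_that("the kernel field moves a fiducial at a source point like that point", {
  p <- bump_pair(200L)
  fit <- cpd_nonrigid(p$src, p$tgt)
  ids <- c(3L, 57L, 120L)
  fids <- fiducial_set(paste0("m", ids), p$src[ids, , drop = FALSE])
  moved <- apply_displacement_to_fiducials(fids, fit)
  got <- as.matrix(moved[, c("x", "y", "z")])
  want <- p$src[ids, ] + fit$displacements[ids, ]
  expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("tidy and glance summarise the displacement field", {
  p <- bump_pair(120L)
  fit <- cpd_nonrigid(p$src, p$tgt)
  td <- tidy(fit)
  expect_identical(nrow(td), 120L)
  expect_named(td, c("idx", "ux", "uy", "uz"))
  gl <- glance(fit)
  expect_identical(gl$n_points, 120L)
  expect_gt(gl$mean_displacement, 0)
})
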