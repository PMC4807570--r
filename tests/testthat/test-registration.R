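# structured test volume with enough texture for phase correlation
reg_volume <- function(seed = 1, d = c(16, 32, 32)) {
  set.seed(seed)
  v <- array(0, d)
  v[5:12, 8:24, 8:24] <- 1
  v[7:10, 12:20, 12:20] <- 2.5
  v[6, 10, 10] <- 4
  v + array(rnorm(prod(d), 0, 0.01), d)
}

test_that("identity cases are exact", {
  v <- reg_volume()
  tr <- estimate_transform(v, v)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(tr$scale, c(1, 1, 1))
  expect_identical(resample_volume(v, rigid_scale_transform()), v)
})

test_that("integer shifts are recovered exactly on noise-free volumes", {
  v <- reg_volume()
  v <- round(v, 1)                      # noise-free piecewise content
  mv <- apply_shrinkage(v, rigid_scale_transform(c(0, 3, -2), 1))
  tr <- estimate_transform(mv, v)
  expect_equal(tr$translation, c(0, 3, -2), tolerance = 1e-6)
  aligned <- resample_volume(mv, tr)
  # interior agrees exactly after undoing an integer shift
  expect_equal(aligned[3:14, 5:28, 5:28], v[3:14, 5:28, 5:28],
               tolerance = 1e-9)
  # with mild noise the estimate stays within a tenth of a voxel
  vn <- reg_volume(2)
  mvn <- apply_shrinkage(vn, rigid_scale_transform(c(0, 3, -2), 1))
  expect_lt(max(abs(estimate_transform(mvn, vn)$translation - c(0, 3, -2))),
            0.1)
})

test_that("sub-voxel shifts are recovered within half a voxel", {
  v <- reg_volume()
  for (t0 in list(c(0, 0.5, 0), c(0.4, -0.5, 0.3))) {
    mv <- apply_shrinkage(v, rigid_scale_transform(t0, 1))
    tr <- estimate_transform(mv, v)
    expect_lt(max(abs(tr$translation - t0)), 0.5)
  }
})

test_that("translation recovery tolerates noise at 5% of tissue mu", {
  ph <- build_root_phantom(
    small_phantom_spec(shrinkage = rigid_scale_transform(c(0, 1, 1), 1),
                       noise = list(model = "gaussian",
                                    sigma = 0.05 * 0.85)))
  tr <- estimate_transform(ph$below, ph$above)
  expect_lt(max(abs(tr$translation - c(0, 1, 1))), 1)
})

test_that("round-trip resampling inverts on smooth volumes", {
  d <- c(12, 24, 24)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  smooth <- array(exp(-((g$z - 6)^2 / 18 + (g$y - 12)^2 / 60 +
                          (g$x - 12)^2 / 60)), d)
  tr <- rigid_scale_transform(c(0.3, -0.6, 0.4), 1)
  back <- resample_volume(resample_volume(smooth, tr),
                          invert_transform(tr))
  core <- back[3:10, 5:20, 5:20] - smooth[3:10, 5:20, 5:20]
  # bound set by two passes of trilinear interpolation on this curvature
  expect_lt(max(abs(core)), 0.05)
  # transform composed with its inverse is the identity
  ti <- invert_transform(tr)
  expect_equal(tr$scale * ti$scale, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(tr$scale * ti$translation + tr$translation, c(0, 0, 0),
               tolerance = 1e-6)
})

test_that("registration suppresses subtraction artifacts >= 5x", {
  sp <- small_phantom_spec(n_yttria_blobs = 0,
                           shrinkage = rigid_scale_transform(c(0, 1, 1), 1))
  ph <- build_root_phantom(sp)
  unreg <- sum(abs(kes_subtract(ph$above, ph$below)) >= 3)
  tr <- estimate_transform(ph$below, ph$above)
  reg <- sum(abs(kes_subtract(ph$above,
                              resample_volume(ph$below, tr))) >= 3)
  expect_gt(unreg, 0)
  expect_lt(reg * 5, unreg)
})

test_that("degenerate inputs are rejected; shapes preserved", {
  v <- reg_volume()
  expect_error(estimate_transform(array(1, dim(v)), v), "constant")
  expect_error(estimate_transform(v[1:8, , ], v), "shape")
  out <- resample_volume(v, rigid_scale_transform(c(0.2, 0.1, 0), 0.99))
  expect_identical(dim(out), dim(v))
})

test_that("global scale search recovers an applied scale", {
  d <- c(24, 96, 96)
  g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  v <- array(0, d)
  v[(g$z - 12)^2 / 9 + (g$y - 48)^2 / 900 + (g$x - 48)^2 / 900 <= 1] <- 1
  v[8:16, 20:30, 60:80] <- 2.2
  v[5:20, 70:80, 15:25] <- 1.6
  tr0 <- rigid_scale_transform(c(0, 0.5, -0.5), 0.99)
  mv <- apply_shrinkage(v, tr0)
  tr <- estimate_transform(mv, v, estimate_scale = TRUE)
  # within one step of the coarse scale grid (0.0025)
  expect_equal(tr$scale[1], 0.99, tolerance = 0.003)
  aligned <- resample_volume(mv, tr)
  expect_gt(cor(as.vector(aligned), as.vector(v)), 0.98)
})
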