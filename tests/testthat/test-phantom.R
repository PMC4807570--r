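test_that("particle sampler reproduces the TEM size statistics", {
  pop <- particle_population()
  tubes <- sample_particles(10000, pop, seed = 1, type = "nanotube")
  se_d <- 8.6 / sqrt(10000)
  expect_lt(abs(mean(tubes$diameter_nm) - 31.3), 3 * se_d)
  se_l <- 77.3 / sqrt(10000)
  expect_lt(abs(mean(tubes$length_nm) - 206.3), 3 * se_l)
  # convergence of moments at n = 1e5 within 2%
  big <- sample_particles(1e5, pop, seed = 2, type = "irregular")
  expect_equal(mean(big$size_nm), 64.9, tolerance = 0.02)
  expect_equal(sd(big$size_nm), 16.9, tolerance = 0.02)
})

test_that("particle sampler is deterministic, truncated and validated", {
  pop <- particle_population()
  a <- sample_particles(500, pop, seed = 7)
  b <- sample_particles(500, pop, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$diameter_nm > 0, na.rm = TRUE))
  expect_true(all(a$length_nm > 0, na.rm = TRUE))
  expect_true(all(a$size_nm > 0, na.rm = TRUE))
  expect_setequal(unique(a$type), c("nanotube", "irregular"))
  # truncation visible on a population with heavy negative mass
  low <- particle_population(diameter_mean = 1, diameter_sd = 5)
  d <- sample_particles(2000, low, seed = 3, type = "nanotube")$diameter_nm
  expect_true(all(d > 0))
  expect_error(sample_particles(0), "count")
})

test_that("construction identity holds exactly before shrinkage/noise", {
  ph <- build_root_phantom(
    small_phantom_spec(shrinkage = rigid_scale_transform(c(0, 0, 0), 1)))
  idx <- ph$truth$yttria > 0
  expect_gt(sum(idx), 0)
  delta <- (ph$above - ph$below)[idx]
  expect_equal(delta, ph$truth$concentration[idx] * ph$delta_mu_rho / 1000,
               tolerance = 1e-12)
  # edge jump ratio of the yttria-only contribution is the table ratio
  expect_equal(ph$edge_ratio,
               mass_attenuation(yttria_compound(), 17.2) /
                 mass_attenuation(yttria_compound(), 16.5))
})

test_that("ground truth masks are disjoint and consistent", {
  ph <- build_root_phantom(small_phantom_spec())
  y <- ph$truth$yttria; m <- ph$truth$mineral; t <- ph$truth$tissue
  expect_equal(sum(y & m), 0)
  expect_equal(sum(y & t), 0)
  expect_equal(sum(m & t), 0)
  expect_true(all(ph$truth$concentration[y == 0] == 0))
  expect_true(all(ph$truth$concentration[y == 1] >=
                    ph$spec$concentration_range[1]))
  expect_identical(dim(y), dim(ph$above))
})

test_that("yttria-free phantom attenuates less above the edge everywhere", {
  ph <- build_root_phantom(
    small_phantom_spec(n_yttria_blobs = 0,
                       shrinkage = rigid_scale_transform(c(0, 0, 0), 1)))
  expect_true(all(ph$above <= ph$below + 1e-12))
  expect_equal(sum(ph$truth$yttria), 0)
})

test_that("phantom generation is reproducible bit-for-bit under a seed", {
  a <- build_root_phantom(small_phantom_spec(seed = 5))
  b <- build_root_phantom(small_phantom_spec(seed = 5))
  expect_identical(a$above, b$above)
  expect_identical(a$below, b$below)
  expect_identical(a$truth$concentration, b$truth$concentration)
  c <- build_root_phantom(small_phantom_spec(seed = 6))
  expect_false(identical(a$above, c$above))
})

test_that("inconsistent phantom specs are rejected", {
  expect_error(build_root_phantom(
    small_phantom_spec(concentration_range = c(0.5, 1))),
    "display window")
  expect_error(phantom_spec(mineral_mu = 5), "mineral_mu")
  expect_error(phantom_spec(shrinkage = rigid_scale_transform(0:2, 1.15)))
})

test_that("apply_shrinkage moves content as specified", {
  ph <- build_root_phantom(
    small_phantom_spec(shrinkage = rigid_scale_transform(c(0, 0, 0), 1)))
  v <- ph$above
  expect_identical(apply_shrinkage(v, rigid_scale_transform(c(0, 0, 0), 1)), v)
  # pure integer translation (0,0,2): content shifted exactly 2 in x
  sh <- apply_shrinkage(v, rigid_scale_transform(c(0, 0, 2), 1))
  expect_identical(sh[, , 3:dim(v)[3]], v[, , 1:(dim(v)[3] - 2)])
  expect_true(all(sh[, , 1:2] == 0))
  # subtraction of shifted minus unshifted tissue: paired bright/dark rims
  rim <- sh - v
  expect_gt(max(rim), 0.3)
  expect_lt(min(rim), -0.3)
})

test_that("noise models behave as declared", {
  v <- array(runif(30^3, 0.5, 1), c(30, 30, 30))
  expect_identical(add_noise(v, "none"), v)
  expect_identical(add_noise(v, "gaussian", seed = 1, sigma = 0), v)
  g <- add_noise(v, "gaussian", seed = 1, sigma = 0.1)
  expect_equal(sd(g - v), 0.1, tolerance = 0.05)
  expect_equal(mean(g - v), 0, tolerance = 0.005)
  expect_identical(add_noise(v, "gaussian", seed = 1, sigma = 0.1), g)
  p <- add_noise(v, "poisson", seed = 2, I0 = 1e5)
  expect_equal(mean(p), mean(v), tolerance = 0.01)
  expect_gt(sd(p - v), 0)
  expect_error(add_noise(v, "bogus"), "arg")
})
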