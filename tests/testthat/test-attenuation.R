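csv_table <- read.csv(system.file("extdata", "mass_attenuation_10_25keV.csv",
                                  package = "kescan"))
lookup <- function(el, e)
  csv_table$mu_over_rho_cm2_g[csv_table$element == el &
                              csv_table$energy_keV == e]

test_that("mixture rule reproduces hand-computed mass fractions", {
  # Y2O3 mass fractions from atomic masses: wY = 2*88.906/225.81
  wY <- 2 * 88.906 / (2 * 88.906 + 3 * 15.999)
  wO <- 1 - wY
  for (e in c(16.5, 17.2)) {
    expected <- wY * lookup("Y", e) + wO * lookup("O", e)
    expect_equal(mass_attenuation(yttria_compound(), e), expected,
                 tolerance = 1e-6)
  }
  # single-element compound at a grid energy is the tabulated value
  oxy <- compound_spec(c(O = 1), 1.43e-3)
  expect_equal(mass_attenuation(oxy, 16), lookup("O", 16))
  # doubling all counts leaves mass fractions (and mu/rho) unchanged
  y2o3 <- compound_spec(c(Y = 2, O = 3), 5.01)
  y4o6 <- compound_spec(c(Y = 4, O = 6), 5.01)
  expect_equal(mass_attenuation(y2o3, 17.2), mass_attenuation(y4o6, 17.2))
})

test_that("yttria K-edge contrast is at least a factor of 5", {
  mu <- linear_attenuation(yttria_compound(), c(16.5, 17.2))
  expect_gte(mu[2] / mu[1], 5)
  # density cancels: linear ratio equals mass ratio
  mr <- mass_attenuation(yttria_compound(), c(16.5, 17.2))
  expect_equal(mu[2] / mu[1], mr[2] / mr[1])
})

test_that("interpolation never bridges the K-edge and is monotone per side", {
  y <- compound_spec(c(Y = 1), 4.47)
  below <- mass_attenuation(y, seq(15, 17.03, length.out = 25))
  above <- mass_attenuation(y, seq(17.05, 20, length.out = 25))
  expect_true(all(diff(below) < 0))
  expect_true(all(diff(above) < 0))
  # values just below the edge stay on the low branch
  expect_lt(mass_attenuation(y, 17.03), 40)
  expect_gt(mass_attenuation(y, 17.05), 90)
})

test_that("water-like compound matches independent tabulation", {
  water <- compound_spec(c(H = 2, O = 1), 1.0)
  # 1.2028 cm^2/g at 17 keV, frozen from an independent standard
  # cross-section library evaluation
  expect_equal(mass_attenuation(water, 17.0), 1.2028, tolerance = 0.02)
  expect_equal(linear_attenuation(water, 17.0),
               mass_attenuation(water, 17.0))
})

test_that("linear attenuation handles degenerate density", {
  void <- compound_spec(c(O = 1), 0)
  expect_identical(linear_attenuation(void, 17.0), 0)
})

test_that("transmission follows Beer-Lambert", {
  expect_identical(transmission(3.2, 0), 1.0)
  expect_equal(transmission(log(2), 1), 0.5)
  # the published calibration pair (67% / 15%) implies the edge jump
  expect_equal(log(0.15) / log(0.67), 4.735, tolerance = 1e-3)
  # strictly decreasing and multiplicative over thickness
  mus <- seq(0.5, 12, length.out = 10)
  expect_true(all(diff(transmission(mus, 0.1)) < 0))
  expect_equal(transmission(2.5, 0.3 + 0.4),
               transmission(2.5, 0.3) * transmission(2.5, 0.4))
  expect_error(transmission(-1, 1), "non-negative")
  expect_error(transmission(1, -1), "non-negative")
})

test_that("kedge_delta_mu_rho exposes both sources", {
  expect_identical(kedge_delta_mu_rho("paper_implied"), 68.0)
  tab <- kedge_delta_mu_rho("table")
  expect_gt(tab, 0)
  # the two sources agree within a factor of 2
  expect_lt(max(tab, 68) / min(tab, 68), 2)
})

test_that("range and lookup errors are raised", {
  expect_error(mass_attenuation(yttria_compound(), 9), "outside")
  expect_error(mass_attenuation(yttria_compound(), 26), "outside")
  expect_error(compound_spec(c(Xx = 1), 1), "unknown element")
  expect_error(compound_spec(c(Y = 1.5), 1), "positive integers")
  expect_error(compound_spec(c(Y = 2, O = 3), -1), "non-negative")
})
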