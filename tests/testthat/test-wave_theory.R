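test_that("dispersion solver reproduces known wavelengths and limits", {
  # Mistral gauge conditions: 10-s wave in 94 m of water is nearly deep
  ds <- solve_dispersion(T = 10, H = 94)
  expect_equal(ds$lam, 156.0, tolerance = 1e-3)
  expect_equal(ds$regime, "deep")
  expect_lt(ds$residual, 1e-10)

  # deep-water limit: kappa -> sigma^2/g
  ds_deep <- solve_dispersion(T = 5, H = 5000)
  expect_equal(ds_deep$kappa, (2 * pi / 5)^2 / 9.81, tolerance = 1e-10)

  # shallow-water limit: phase speed -> sqrt(gH)
  ds_sh <- solve_dispersion(T = 600, H = 2)
  expect_equal(ds_sh$sigma / ds_sh$kappa, sqrt(9.81 * 2), tolerance = 1e-4)
  expect_equal(ds_sh$regime, "shallow")

  expect_error(solve_dispersion(-1, 10), "must be > 0")
  expect_error(solve_dispersion(10, 0), "must be > 0")
})

test_that("dispersion residual stays below tolerance over random (T, H) draws", {
  set.seed(42)
  for (i in 1:1000) {
    T <- runif(1, 2, 25); H <- runif(1, 0.5, 500)
    ds <- solve_dispersion(T, H)
    sigma <- 2 * pi / T
    expect_lt(abs(sigma^2 - 9.81 * ds$kappa * tanh(ds$kappa * H)) / sigma^2, 1e-10)
    expect_equal(ds$lam * ds$kappa, 2 * pi, tolerance = 1e-12)
  }
})

test_that("deep-water wavelength follows g T^2 / (2 pi)", {
  expect_equal(deep_water_wavelength(10.7), 9.81 * 10.7^2 / (2 * pi))
  expect_equal(deep_water_wavelength(10.7), 178.8, tolerance = 1e-3)
  expect_equal(deep_water_wavelength(10.4), 168.9, tolerance = 1e-3)
  expect_equal(deep_water_wavelength(0), 0)
  expect_error(deep_water_wavelength(-2), ">= 0")
})

test_that("shoaling shortens waves as depth decreases and approaches the deep limit", {
  # the two field-site chains (printed deep-water wavelengths 180 m and 168 m)
  expect_equal(shoal_wavelength(180, 2), 47, tolerance = 0.5)
  expect_equal(shoal_wavelength(180, 7), 85, tolerance = 0.5)
  expect_equal(shoal_wavelength(168, 7), 82, tolerance = 0.5)
  expect_equal(shoal_wavelength(168, 25), 137, tolerance = 0.5)

  H <- seq(1, 50, by = 0.5)
  lam <- shoal_wavelength(120, H)
  expect_true(all(diff(lam) > 0))        # monotone in depth
  expect_true(all(lam <= 120))
  expect_equal(shoal_wavelength(120, 5000), 120, tolerance = 1e-6)
})

test_that("shoaling agrees with the dispersion relation under a conserved period", {
  for (T in c(6, 9, 14)) {
    lam_inf <- deep_water_wavelength(T)
    for (H in c(2, 8, 30)) {
      expect_equal(shoal_wavelength(lam_inf, H),
                   solve_dispersion(T, H)$lam, tolerance = 1e-6)
    }
  }
})

test_that("bottom kinematics reproduce the gauge example and the quadratic stress law", {
  ds <- solve_dispersion(10, 94)
  bk <- bottom_kinematics(Hs = 8, T = 10, kappa = ds$kappa, H = 94)
  expect_equal(bk$A_b, 8 / (2 * sinh(ds$kappa * 94)), tolerance = 1e-12)
  expect_equal(bk$A_b, 0.181, tolerance = 0.01)
  expect_equal(bk$U_b, 0.114, tolerance = 0.01)
  expect_equal(bk$tau_b, 0.5 * 1025 * 0.05 * bk$U_b^2, tolerance = 1e-12)

  # zero wave height -> zero kinematics
  bk0 <- bottom_kinematics(0, 10, ds$kappa, 94)
  expect_identical(unlist(bk0), c(A_b = 0, U_b = 0, tau_b = 0))

  # doubling U_b quadruples tau_b
  bk2 <- bottom_kinematics(16, 10, ds$kappa, 94)
  expect_equal(bk2$tau_b / bk$tau_b, 4, tolerance = 1e-12)

  # inconsistent dispersion triple rejected
  expect_error(bottom_kinematics(8, 10, ds$kappa * 1.2, 94), "inconsistent")
})

test_that("analytic basic-state fields satisfy the free-surface wave identities", {
  wp <- wave_parameters(a = 0.4, T = 8)
  H0 <- 9
  ds <- solve_dispersion(8, H0)
  x <- 13.7; ts <- seq(0, 8, length.out = 200)

  # surface amplitude equals a at any x (rms of a sinusoid is amp/sqrt(2);
  # uniform full-period sampling makes this exact)
  eta <- vapply(ts[-length(ts)], function(t)
    basic_wave_fields(wp, ds, H0, x, 0, t)$eta0, numeric(1))
  expect_equal(sqrt(2 * mean(eta^2)), wp$a, tolerance = 1e-12)

  # bottom velocity amplitude sigma*a/sinh(kH0); w vanishes at the bed
  ub <- vapply(ts[-length(ts)], function(t)
    basic_wave_fields(wp, ds, H0, x, -H0, t)$u0, numeric(1))
  expect_equal(sqrt(2 * mean(ub^2)), wp$sigma * wp$a / sinh(ds$kappa * H0),
               tolerance = 1e-12)
  wb <- vapply(ts, function(t) basic_wave_fields(wp, ds, H0, x, -H0, t)$w0,
               numeric(1))
  expect_true(all(abs(wb) < 1e-14))

  # Laplace identity at random points via central differences
  set.seed(7)
  h <- 1e-4
  for (i in 1:20) {
    xi <- runif(1, -50, 50); zi <- runif(1, -H0 + 0.5, -0.5); ti <- runif(1, 0, 8)
    f <- function(x, z) basic_wave_fields(wp, ds, H0, x, z, ti)$phi0
    lap <- (f(xi + h, zi) - 2 * f(xi, zi) + f(xi - h, zi)) / h^2 +
           (f(xi, zi + h) - 2 * f(xi, zi) + f(xi, zi - h)) / h^2
    expect_lt(abs(lap) / max(abs(f(xi, zi)), 1e-10), 1e-5)
  }

  # period-mean of u0^2 at the bed equals U_b^2 / 2
  Ub <- wp$sigma * wp$a / sinh(ds$kappa * H0)
  expect_equal(mean(ub^2), Ub^2 / 2, tolerance = 1e-10)
  expect_error(basic_wave_fields(wp, ds, H0, 0, -H0 - 1, 0), "water column")
})
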