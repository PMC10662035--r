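test_that("sponge profile is zero inside, smooth at the border and maximal at the edge", {
  g <- sim_grid(lam = 70, n_lambda_interior = 6, n_lambda_sponge = 2,
                nodes_per_lambda = 32)
  gam <- build_sponge(g, gamma_max = 1.3, exponent = 2)
  expect_true(all(gam[g$interior] == 0))
  expect_equal(max(gam), 1.3, tolerance = 1e-2)   # edge node is dx short of L
  # quadratic ramp: finite-difference slope vanishes at the interior border
  ib <- max(which(g$x < -(g$L - g$dL)))
  expect_lt((gam[ib] - gam[ib + 1]) / g$dx, 1e-3)
  expect_true(all(diff(gam[g$x <= 0]) <= 0))      # nondecreasing toward edges
  expect_error(build_sponge(g, 1, exponent = 1), ">= 2")
})

test_that("dtn_map matches the closed-form single-mode identities", {
  H0 <- 7
  nx <- 64
  kvec <- (2 * pi / 400) * c(0:(nx / 2 - 1), -(nx / 2):-1)
  j <- 5  # some positive-k mode
  phis <- complex(real = numeric(nx)); phis[j] <- 2 + 1i
  wb0 <- complex(real = numeric(nx))
  k <- abs(kvec[j])

  # surface-driven: classical flat-bottom Dirichlet-to-Neumann relation
  m <- dtn_map(phis, wb0, H0, kvec)
  expect_equal(m$ws_hat[j], k * tanh(k * H0) * phis[j], tolerance = 1e-12)

  # bottom-forced
  wb <- wb0; wb[j] <- 1 - 2i
  m2 <- dtn_map(0 * phis, wb, H0, kvec)
  expect_equal(m2$ws_hat[j], wb[j] / cosh(k * H0), tolerance = 1e-12)

  # k = 0 limits
  phis0 <- complex(real = numeric(nx)); phis0[1] <- 3
  wbk0 <- complex(real = numeric(nx)); wbk0[1] <- 0.5
  m0 <- dtn_map(phis0, wbk0, H0, kvec)
  expect_equal(m0$ws_hat[1], wbk0[1])
  expect_equal(m0$phib_hat[1], phis0[1] - wbk0[1] * H0)
  expect_equal(m0$ub_hat[1], 0 + 0i)

  expect_error(dtn_map(c(phis[1], NA), wb0[1:2], H0, kvec[1:2]), "NaN")
})

test_that("dtn_map agrees with a finite-difference solve of the Laplace strip", {
  # oracle: second-order FD in z for each Fourier mode of the strip problem
  # phi'' = k^2 phi, phi(0) = phis, phi'(-H0) = wb; returns phi'(0)
  fd_ws <- function(phis, wb, k, H0, nz = 2000) {
    dz <- H0 / nz
    # unknowns phi_1..phi_nz at z = -dz, ..., -H0 (phi_0 = phis known)
    d_main <- rep(-2 - (k * dz)^2, nz)
    A <- matrix(0, nz, nz)
    for (i in 1:nz) {
      A[i, i] <- d_main[i]
      if (i > 1) A[i, i - 1] <- 1
      if (i < nz) A[i, i + 1] <- 1
    }
    b <- rep(0 + 0i, nz)
    b[1] <- -phis
    # Neumann at the bed via ghost node: phi_{nz+1} = phi_{nz-1} - 2 dz wb
    A[nz, nz - 1] <- 2
    b[nz] <- 2 * dz * wb
    phi <- solve(A, b)
    # one-sided second-order derivative at the surface
    (3 * phis - 4 * phi[1] + phi[2]) / (2 * dz)
  }
  set.seed(5)
  H0 <- 6
  L <- 500
  nmodes <- 16
  for (m in 1:nmodes) {
    k <- 2 * pi / L * m
    phis <- complex(real = rnorm(1), imaginary = rnorm(1))
    wb <- complex(real = rnorm(1), imaginary = rnorm(1))
    kvec <- c(0, k)
    res <- dtn_map(c(0, phis), c(0, wb), H0, kvec)
    ws_fd <- fd_ws(phis, wb, k, H0)
    expect_lt(Mod(res$ws_hat[2] - ws_fd) / Mod(ws_fd), 1e-4)
  }
})

test_that("bottom source has the flux-form properties and Bragg side-bands", {
  g <- sim_grid(lam = 70, n_lambda_interior = 6, n_lambda_sponge = 2,
                nodes_per_lambda = 64)
  kap <- 2 * pi / 70
  u0b <- 0.3 * cos(kap * g$x)

  expect_true(all(bottom_source(numeric(g$nx), numeric(g$nx), u0b, 2, g) == 0))

  # static bed at 2k against flow at k: side-bands at k and 3k only
  n1 <- 0.01 * cos(2 * kap * g$x)
  wb <- bottom_source(n1, numeric(g$nx), u0b, s = 2, grid = g)
  pr <- function(k) sqrt(sum(interior_projection(wb, g, k)^2))
  expect_gt(pr(kap), 1e-6)
  expect_gt(pr(3 * kap), 1e-6)
  expect_lt(pr(2 * kap), 1e-12)

  # flux term integrates to zero: domain integral tracks s * d/dt int(n1)
  dn1 <- 0.002 * (1 + sin(3 * kap * g$x))
  wb2 <- bottom_source(n1, dn1, u0b, s = 2, grid = g)
  expect_equal(mean(wb2), 2 * mean(dn1), tolerance = 1e-12)
})

test_that("trailing-period stress average obeys the quadratic expansion", {
  nsteps <- 128; nxp <- 8
  tgrid <- seq(0, 2 * pi, length.out = nsteps + 1)[1:nsteps]
  x <- seq(0, 2 * pi, length.out = nxp + 1)[1:nxp]
  kap <- 3
  u0 <- outer(tgrid, x, function(t, x) 0.4 * cos(kap * x - t))

  expect_identical(averaged_shear_perturbation(u0, 0 * u0),
                   numeric(nxp))

  # u1 = eps * u0  ->  tau_b1 = 2 * eps * tau_b0
  eps <- 0.01
  tb0 <- 0.5 * 1025 * 0.05 * 0.4^2            # 0.5 rho f_w U^2
  tb1 <- averaged_shear_perturbation(u0, eps * u0)
  expect_equal(tb1, rep(2 * eps * tb0, nxp), tolerance = 1e-10)

  # standing-wave perturbation yields a stationary stress pattern at 2k
  u1 <- outer(tgrid, x, function(t, x) 0.05 * cos(kap * x + t))
  tb <- averaged_shear_perturbation(u0, u1)
  # closed form: 2 rho f_w <u0 u1> = rho f_w U0 U1 cos(2 k x)
  expect_equal(tb, 1025 * 0.05 * 0.4 * 0.05 * cos(2 * kap * x), tolerance = 1e-8)
})

test_that("seagrass tendency reduces to the expected linearizations", {
  sp <- seagrass_params()
  wp <- wave_parameters(a = 0.3, T = 8)
  bs <- uniform_equilibrium(0.3, 8, wp, sp)
  g <- sim_grid(lam = 2 * pi / bs$kappa, n_lambda_interior = 6,
                n_lambda_sponge = 2, nodes_per_lambda = 32)
  zero <- numeric(g$nx)

  expect_true(all(seagrass_tendency(zero, zero, bs, sp, g) == 0))

  # uniform small perturbation decays at the local linear rate
  eps <- 1e-8
  d <- seagrass_tendency(rep(eps, g$nx), zero, bs, sp, g)
  rate <- -bs$omega0 + 2 * sp$alpha * bs$n0 - 3 * sp$beta * bs$n0^2
  expect_equal(d / eps, rep(rate, g$nx), tolerance = 1e-6)
  expect_lt(rate, 0)   # the uniform vegetated state is locally stable

  # pure stress forcing acts through -omega_c * tau_b1 * n0 at n1 = 0
  tau <- 0.01 * cos(2 * bs$kappa * g$x)
  d2 <- seagrass_tendency(zero, tau, bs, sp, g)
  expect_equal(d2, -sp$omega_c * tau * bs$n0, tolerance = 1e-12)
})

test_that("null configurations produce no wave perturbation and no pattern", {
  # zero initial perturbation stays exactly zero
  cfg <- quick_config(n1_init = numeric(6 * 32 + 2 * 2 * 32))
  res <- run_simulation(cfg)
  expect_true(all(res$eta1 == 0))
  expect_true(all(res$n1 == 0))
  expect_true(all(res$tau_b1 == 0))

  # s = 0: no topography, waves never forced, noise decays locally
  cfg_s0 <- quick_config(sp = seagrass_params(s = 0), seed = 2)
  res_s0 <- run_simulation(cfg_s0)
  expect_true(all(res_s0$eta1 == 0))
  p0 <- pattern_spectrum(res_s0$n1_initial, res_s0$grid, res_s0$kappa)
  p1 <- pattern_spectrum(res_s0$n1, res_s0$grid, res_s0$kappa)
  i2k <- which.min(abs(p0$k - 2 * res_s0$kappa))
  expect_lt(p1$amplitude[i2k], p0$amplitude[i2k])

  # omega_c = 0: one-way coupling, no stress feedback, pattern decays
  cfg_wc <- quick_config(sp = seagrass_params(omega_c = 1e-30), seed = 2)
  res_wc <- run_simulation(cfg_wc)
  q0 <- pattern_spectrum(res_wc$n1_initial, res_wc$grid, res_wc$kappa)
  q1 <- pattern_spectrum(res_wc$n1, res_wc$grid, res_wc$kappa)
  expect_lt(q1$amplitude[i2k], q0$amplitude[i2k])
})

test_that("free single-mode oscillation matches the dispersion relation to 1e-4", {
  sp <- seagrass_params()
  wp <- wave_parameters(a = 0, T = 8)
  bs <- uniform_equilibrium(0, 8, wp, sp)
  g <- sim_grid(lam = 2 * pi / bs$kappa, n_lambda_interior = 6,
                n_lambda_sponge = 2, nodes_per_lambda = 32)
  m <- 14                      # mode index on the periodic domain
  km <- 2 * pi / (2 * g$L) * m
  probe <- which.max(cos(km * g$x))
  cfg <- sim_config(wp = wp, sp = sp, topography_frozen = TRUE,
                    n1_init = numeric(g$nx), eta1_init = cos(km * g$x),
                    gamma_max = 0, grid = g, basic_state = bs,
                    n_periods = 10, spinup_periods = 0, probe_node = probe)
  res <- run_simulation(cfg)
  e <- res$probe[, "eta1"]; tt <- res$probe[, "t"]
  # zero crossings with linear interpolation give the oscillation period
  idx <- which(e[-1] * e[-length(e)] < 0)
  tc <- tt[idx] - e[idx] * (tt[idx + 1] - tt[idx]) / (e[idx + 1] - e[idx])
  omega_meas <- pi * (length(tc) - 1) / (tc[length(tc)] - tc[1])
  omega_th <- sqrt(wp$g * km * tanh(km * bs$H0))
  expect_equal(omega_meas, omega_th, tolerance = 1e-4)
})

test_that("sponge layers absorb an incident packet to below 1e-3", {
  sp <- seagrass_params()
  wp <- wave_parameters(a = 0, T = 8)
  bs <- uniform_equilibrium(0, 8, wp, sp)
  lam <- 2 * pi / solve_dispersion(8, bs$H0)$kappa
  g <- sim_grid(lam, n_lambda_interior = 8, n_lambda_sponge = 2,
                nodes_per_lambda = 32)
  # spectrally constructed one-way (rightward) packet centred at the origin
  kap <- 2 * pi / lam
  env <- exp(-(g$x / (1.5 * lam))^2)
  target <- env * cos(kap * g$x)
  hat <- stats::fft(target)
  pos <- c(FALSE, g$kvec[-1] > 0)
  hat[!pos] <- 0
  omega_k <- sqrt(wp$g * abs(g$kvec) * tanh(abs(g$kvec) * bs$H0))
  phat <- hat * 0
  phat[pos] <- -1i * wp$g * hat[pos] / omega_k[pos]
  eta0 <- 2 * Re(stats::fft(hat, inverse = TRUE)) / g$nx
  phi0 <- 2 * Re(stats::fft(phat, inverse = TRUE)) / g$nx
  cfg <- sim_config(wp = wp, sp = sp, topography_frozen = TRUE,
                    n1_init = numeric(g$nx), eta1_init = eta0,
                    phis1_init = phi0, grid = g, basic_state = bs,
                    n_periods = 16, spinup_periods = 0)
  res <- run_simulation(cfg)
  # after ~16 periods the packet has entered the right sponge; any interior
  # signal is reflection from the absorber
  expect_lt(max(abs(res$eta1[g$interior])) / max(abs(eta0)), 1e-3)
})

test_that("pattern statistics are robust to refinement of dt and dx", {
  sp <- seagrass_params()
  a_star <- critical_amplitude(8, wave_parameters(T = 8), sp)
  wp <- wave_parameters(a = 0.96 * a_star, T = 8)
  bs <- uniform_equilibrium(wp$a, 8, wp, sp)
  # deterministic initial condition: the Bragg mode rounded to a domain
  # harmonic, built analytically on each grid
  run_ref <- function(npl, dtf) {
    g <- sim_grid(2 * pi / bs$kappa, n_lambda_interior = 10,
                  n_lambda_sponge = 2, nodes_per_lambda = npl)
    k2 <- 2 * pi / (2 * g$L) * round(2 * bs$kappa * 2 * g$L / (2 * pi))
    n1 <- ifelse(g$interior, 1e-5 * cos(k2 * g$x), 0)
    cfg <- sim_config(wp = wp, sp = sp, grid = g, basic_state = bs,
                      n1_init = n1, dt_frac = dtf, n_periods = 10)
    run_simulation(cfg)
  }
  r0 <- run_ref(64, 1 / 128)
  r_dt <- run_ref(64, 1 / 256)
  r_dx <- run_ref(128, 1 / 128)
  s0 <- pattern_spectrum(r0$n1, r0$grid, r0$kappa)
  s_dt <- pattern_spectrum(r_dt$n1, r_dt$grid, r_dt$kappa)
  s_dx <- pattern_spectrum(r_dx$n1, r_dx$grid, r_dx$kappa)
  i <- which.min(abs(s0$k - 2 * r0$kappa))
  expect_equal(s0$k_dominant, s_dt$k_dominant, tolerance = 1e-12)
  expect_equal(s_dt$amplitude[i] / s0$amplitude[i], 1, tolerance = 0.02)
  # dominant mode at the same wavenumber to within a bin across resolutions
  expect_lt(abs(s_dx$k_dominant - 2 * r0$kappa), s0$dk)
  expect_lt(abs(s0$k_dominant - 2 * r0$kappa), s0$dk)
  i_dx <- which.min(abs(s_dx$k - 2 * r0$kappa))
  expect_equal(s_dx$amplitude[i_dx] / s0$amplitude[i], 1, tolerance = 0.02)
})

test_that("reflection from a frozen patch is independent of the domain length", {
  sp <- seagrass_params()
  wp <- wave_parameters(a = 0.3, T = 8)
  bs <- uniform_equilibrium(0.3, 8, wp, sp)
  lam <- 2 * pi / bs$kappa
  kr <- sapply(c(8, 12), function(nint) {
    g <- sim_grid(lam, n_lambda_interior = nint, n_lambda_sponge = 2,
                  nodes_per_lambda = 32)
    n1 <- ifelse(abs(g$x) < 2 * lam, 0.01 * cos(2 * bs$kappa * g$x), 0)
    cfg <- sim_config(wp = wp, sp = sp, topography_frozen = TRUE, n1_init = n1,
                      grid = g, basic_state = bs, n_periods = 120,
                      stop_on_equilibrium = TRUE, drift_tol = 0.002)
    reflection_coefficient(run_simulation(cfg), require_equilibrium = FALSE)
  })
  expect_lt(abs(kr[2] - kr[1]) / kr[1], 0.01)
})

test_that("scattered wave over a Bragg patch travels against the forcing", {
  sp <- seagrass_params()
  wp <- wave_parameters(a = 0.3, T = 8)
  bs <- uniform_equilibrium(0.3, 8, wp, sp)
  g <- sim_grid(2 * pi / bs$kappa, n_lambda_interior = 8, n_lambda_sponge = 2,
                nodes_per_lambda = 64)
  n1 <- ifelse(g$interior, 0.02 * cos(2 * bs$kappa * g$x), 0)
  cfg <- sim_config(wp = wp, sp = sp, topography_frozen = TRUE, n1_init = n1,
                    grid = g, basic_state = bs, n_periods = 16)
  res <- run_simulation(cfg)
  # directional split per Fourier mode from (eta1, phis1) at one instant:
  # rightgoing p = (eta_hat + i w/g phis_hat)/2, leftgoing q = the conjugate
  # combination, with w the free-wave frequency of that mode
  hat_e <- stats::fft(res$eta1)
  hat_p <- stats::fft(res$phis1)
  band <- which(g$kvec > 0 & abs(g$kvec - res$kappa) < 0.15 * res$kappa)
  om <- sqrt(wp$g * g$kvec[band] * tanh(g$kvec[band] * bs$H0))
  p_right <- (hat_e[band] + (1i * om / wp$g) * hat_p[band]) / 2
  q_left <- (hat_e[band] - (1i * om / wp$g) * hat_p[band]) / 2
  expect_gt(sum(Mod(q_left)^2), 10 * sum(Mod(p_right)^2))
})
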