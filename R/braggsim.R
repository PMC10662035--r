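#' Uniform 1-D simulation grid with sponge margins
#'
#' Builds the periodic horizontal grid used by the scattering simulator: an
#' interior working section flanked by two absorbing sponge layers. The grid
#' spans `[-L, L)` with `nx` uniform nodes; the interior is `|x| < L - dL`.
#'
#' @param lam forcing wavelength used to size the domain \[m\]
#' @param n_lambda_interior interior length in forcing wavelengths
#' @param n_lambda_sponge sponge width in forcing wavelengths (each side)
#' @param nodes_per_lambda nodes per forcing wavelength (>= 32)
#' @return list of class `sim_grid`: `x` node coordinates, `dx`, `L`
#'   half-domain \[m\], `dL` sponge width \[m\], `nx`, `interior` logical mask,
#'   `kvec` spectral wavenumbers \[rad/m\] in FFT order
#' @export
sim_grid <- function(lam, n_lambda_interior = 10, n_lambda_sponge = 2,
                     nodes_per_lambda = 64) {
  if (nodes_per_lambda < 32)
    stop("need at least 32 nodes per forcing wavelength")
  n_lam_tot <- n_lambda_interior + 2 * n_lambda_sponge
  nx <- as.integer(n_lam_tot * nodes_per_lambda)
  if (nx %% 2L != 0L) stop("'nx' must be even")
  L <- n_lam_tot * lam / 2
  dL <- n_lambda_sponge * lam
  if (dL >= L) stop("sponge width must be smaller than the half-domain")
  dx <- 2 * L / nx
  x <- -L + dx * (seq_len(nx) - 1)
  kvec <- (2 * pi / (2 * L)) * c(0:(nx / 2 - 1), -(nx / 2):-1)
  structure(list(x = x, dx = dx, L = L, dL = dL, nx = nx,
                 interior = abs(x) < L - dL, kvec = kvec),
            class = "sim_grid")
}

#' Sponge-layer damping profile
#'
#' A damping coefficient that is zero in the interior and grows smoothly as a
#' power law towards the domain edges:
#' \eqn{\gamma(x) = \gamma_{max} ((|x| - (L - \Delta L)) / \Delta L)^p}
#' for \eqn{|x| > L - \Delta L}, else 0. `exponent >= 2` guarantees a
#' continuous first derivative at the interior border, so outgoing waves enter
#' the absorber without an impedance jump.
#'
#' @param grid [sim_grid()]
#' @param gamma_max peak damping rate at the domain edge \[1/s\]
#' @param exponent power of the ramp (>= 2)
#' @return numeric vector `gamma(x)` \[1/s\] on the grid nodes
#' @export
build_sponge <- function(grid, gamma_max = 1, exponent = 2) {
  if (grid$dL <= 0) stop("sponge width must be positive")
  if (exponent < 2) stop("'exponent' must be >= 2 for a smooth interior border")
  xi <- (abs(grid$x) - (grid$L - grid$dL)) / grid$dL
  gamma_max * pmax(xi, 0)^exponent
}

# numerically safe sech: 2 e^{-x} / (1 + e^{-2x}) for x >= 0
.sech <- function(x) {
  e <- exp(-abs(x))
  2 * e / (1 + e * e)
}

#' Flat-strip Dirichlet-to-Neumann map of the Laplace problem
#'
#' Mode-by-mode exact solution of \eqn{\partial_{xx}\phi + \partial_{zz}\phi = 0}
#' on the strip \eqn{-H_0 < z < 0}, given the surface potential (Fourier
#' coefficients `phis_hat`) and the bottom normal velocity (`wb_hat`). For
#' each mode \eqn{k \ne 0}:
#' \deqn{\hat w_s = |k| \tanh(|k| H_0) \hat\phi_s + \hat w_b / \cosh(|k| H_0)}
#' \deqn{\hat\phi_b = \hat\phi_s / \cosh(|k| H_0) - (\hat w_b/|k|) \tanh(|k| H_0)}
#' \deqn{\hat u_b = i k \hat\phi_b}
#' and for \eqn{k = 0} the analytic limits \eqn{\hat w_s = \hat w_b},
#' \eqn{\hat\phi_b = \hat\phi_s - \hat w_b H_0}, \eqn{\hat u_b = 0}.
#'
#' @param phis_hat complex Fourier coefficients of the surface potential
#'   \[m^2/s\], FFT order
#' @param wb_hat complex Fourier coefficients of the bottom normal velocity
#'   \[m/s\]
#' @param H0 strip depth \[m\]
#' @param kvec wavenumbers in FFT order \[rad/m\]
#' @return list of complex vectors `ws_hat` (surface vertical velocity),
#'   `phib_hat` (bottom potential), `ub_hat` (bottom horizontal velocity)
#' @export
dtn_map <- function(phis_hat, wb_hat, H0, kvec) {
  if (H0 <= 0) stop("'H0' must be > 0")
  if (anyNA(phis_hat) || anyNA(wb_hat))
    stop("NaN in dtn_map inputs (phis_hat/wb_hat)")
  ka <- abs(kvec)
  th <- tanh(ka * H0)
  sch <- .sech(ka * H0)
  tanh_over_k <- ifelse(ka == 0, H0, th / ifelse(ka == 0, 1, ka))
  ws_hat <- ka * th * phis_hat + sch * wb_hat
  phib_hat <- sch * phis_hat - tanh_over_k * wb_hat
  ub_hat <- 1i * kvec * phib_hat
  list(ws_hat = ws_hat, phib_hat = phib_hat, ub_hat = ub_hat)
}

#' Bottom normal-velocity source induced by the moving seagrass bed
#'
#' Linearized kinematic bottom condition, transferred to the flat reference
#' level \eqn{z = -H_0}: the bed moves with the seagrass
#' (\eqn{s\,\partial_t n_1}) and the basic-state bottom flow slides along the
#' modulated bed, giving the flux term \eqn{\partial_x(s\,n_1\,u_{0b})}. The
#' flux form bundles the slope term with the transfer of the basic-state
#' condition to the reference level, and integrates to zero over the domain.
#'
#' @param n1 seagrass density perturbation per node
#' @param dn1_dt its time derivative per node \[1/s\]
#' @param u0b basic-state bottom velocity per node at the current time \[m/s\]
#' @param s topography coefficient \[m per unit density\]
#' @param grid [sim_grid()] (spectral x-derivative)
#' @return bottom normal velocity `wb` per node \[m/s\]
#' @export
bottom_source <- function(n1, dn1_dt, u0b, s, grid) {
  ik <- 1i * grid$kvec
  ik[grid$nx / 2 + 1] <- 0  # drop Nyquist in odd derivative
  flux <- Re(stats::fft(ik * stats::fft(s * n1 * u0b), inverse = TRUE)) / grid$nx
  s * dn1_dt + flux
}

#' Simulation configuration
#'
#' Collects the physical parameters, grid resolution and numerical controls
#' of a coupled (or frozen-topography) scattering run.
#'
#' @param wp [wave_parameters()]: forcing amplitude `a`, period `T` and the
#'   fluid constants
#' @param sp [seagrass_params()]
#' @param n_lambda_interior,n_lambda_sponge,nodes_per_lambda grid sizing, see
#'   [sim_grid()]
#' @param dt_frac hydrodynamic time step as a fraction of the forcing period
#'   (default 1/128; must be <= 1/64)
#' @param n_periods coupled run length in forcing periods
#' @param spinup_periods hydrodynamics-only spin-up before the biological
#'   clock starts (fills the stress-averaging buffer)
#' @param morph_accel morphological acceleration factor `M >= 1`: the seagrass
#'   equation is advanced by `M * dt` per hydrodynamic step, the standard
#'   trick for bridging wave and meadow time scales
#' @param seed integer seed for the initial noise field
#' @param init_noise_rel initial `n1` noise amplitude relative to `n0`
#' @param gamma_max,sponge_exponent sponge profile, see [build_sponge()]
#' @param topography_frozen if `TRUE` the seagrass field is held fixed and
#'   only the wave perturbation evolves (reflection runs)
#' @param n1_init optional initial `n1` field (overrides the noise)
#' @param eta1_init,phis1_init optional initial wave perturbation fields
#'   (default zero); used for free-wave and sponge-absorption tests
#' @param basic_state optional [uniform_equilibrium()] result to use instead
#'   of solving it from `(wp, sp)`; used by reflection scans that inherit the
#'   basic state of the pattern-forming run
#' @param kappa_forcing optional forcing wavenumber \[rad/m\]; if given, the
#'   forcing frequency is taken from the dispersion relation at the basic
#'   state depth `H0` instead of from `wp$T` (reflection scans vary the
#'   forcing wavenumber over a fixed topography)
#' @param grid optional [sim_grid()] to use instead of building one from the
#'   forcing wavelength; reflection scans must keep the grid of the run that
#'   produced the frozen pattern
#' @param stop_on_equilibrium if `TRUE`, stop once the interior wave envelope
#'   drifts by less than `drift_tol` per period over 5 consecutive periods
#' @param drift_tol relative per-period drift defining dynamic equilibrium
#' @param store_snapshots if `TRUE`, keep per-period snapshots of the fields
#' @param probe_node optional node index whose `eta1` value is recorded every
#'   time step (returned as `probe` with columns `t`, `eta1`)
#' @return list of class `sim_config`
#' @export
sim_config <- function(wp = wave_parameters(), sp = seagrass_params(),
                       n_lambda_interior = 20, n_lambda_sponge = 2,
                       nodes_per_lambda = 64, dt_frac = 1 / 128,
                       n_periods = 25, spinup_periods = 5,
                       morph_accel = 1000, seed = 0, init_noise_rel = 1e-4,
                       gamma_max = 1, sponge_exponent = 2,
                       topography_frozen = FALSE, n1_init = NULL,
                       eta1_init = NULL, phis1_init = NULL,
                       basic_state = NULL, kappa_forcing = NULL, grid = NULL,
                       stop_on_equilibrium = FALSE, drift_tol = 0.01,
                       store_snapshots = FALSE, probe_node = NULL) {
  if (dt_frac > 1 / 64) stop("'dt_frac' must be <= 1/64")
  if (morph_accel < 1) stop("'morph_accel' must be >= 1")
  structure(list(wp = wp, sp = sp,
                 n_lambda_interior = n_lambda_interior,
                 n_lambda_sponge = n_lambda_sponge,
                 nodes_per_lambda = nodes_per_lambda,
                 dt_frac = dt_frac, n_periods = n_periods,
                 spinup_periods = spinup_periods, morph_accel = morph_accel,
                 seed = as.integer(seed), init_noise_rel = init_noise_rel,
                 gamma_max = gamma_max, sponge_exponent = sponge_exponent,
                 topography_frozen = topography_frozen, n1_init = n1_init,
                 eta1_init = eta1_init, phis1_init = phis1_init,
                 basic_state = basic_state, kappa_forcing = kappa_forcing,
                 grid = grid,
                 stop_on_equilibrium = stop_on_equilibrium,
                 drift_tol = drift_tol, store_snapshots = store_snapshots,
                 probe_node = probe_node),
            class = "sim_config")
}

# seagrass perturbation tendency: full density equation minus the basic-state
# balance, with the nonlinear facilitation/competition terms retained so that
# growth can saturate
.seagrass_rhs <- function(n1, tau_b1, bs, sp, grid) {
  lin <- -bs$omega0 * n1 + sp$alpha * 2 * bs$n0 * n1 - sp$beta * 3 * bs$n0^2 * n1
  nl <- sp$alpha * n1^2 - sp$beta * (3 * bs$n0 * n1^2 + n1^3)
  stress <- -sp$omega_c * tau_b1 * (bs$n0 + n1)
  k2 <- grid$kvec^2
  disp <- Re(stats::fft(-k2 * stats::fft(n1), inverse = TRUE)) / grid$nx
  lin + nl + stress + sp$delta * disp
}

#' Run a coupled (or frozen-topography) scattering simulation
#'
#' Time-integrates the linearized perturbation hydrodynamics
#' \deqn{\partial_t \phi_{1s} = -g \eta_1 - \gamma \phi_{1s}, \qquad
#'       \partial_t \eta_1 = w_s - \gamma \eta_1}
#' with the surface vertical velocity from the strip Dirichlet-to-Neumann map
#' ([dtn_map()]) forced at the bottom by the seagrass bed ([bottom_source()]),
#' using 4th-order Runge-Kutta at `dt = dt_frac * T`. Unless the topography is
#' frozen, the seagrass perturbation is advanced every hydrodynamic step by
#' the morphologically accelerated density equation, driven by the
#' trailing-period-averaged bed shear stress perturbation
#' \eqn{\tau_{b1} = 2 \rho f_w \langle u_{0b} u_{1b} \rangle}.
#'
#' The run starts with `spinup_periods` of hydrodynamics only (seagrass held
#' at its initial field), which establishes the scattered wave and fills the
#' stress-averaging buffer, after which the biological clock starts at
#' `t = 0`.
#'
#' @param config [sim_config()]
#' @return list of class `sim_result`: the `config`, `basic_state`, `grid`,
#'   sponge profile `gamma`, forcing `kappa`/`sigma`/`lam`, final fields
#'   `eta1`, `phis1`, `n1`, `tau_b1`, the post-noise initial field
#'   `n1_initial`, per-period interior envelope maxima `period_max_eta1`
#'   (\[-\] normalized by `a`), the final period's per-node envelope
#'   `eta1_envelope`, `equilibrated` flag and per-period `n1` snapshots if
#'   requested
#' @export
run_simulation <- function(config) {
  wp <- config$wp; sp <- config$sp
  bs <- config$basic_state
  if (is.null(bs))
    bs <- uniform_equilibrium(wp$a, wp$T, wp, sp, branch = "vegetated")
  if (!bs$exists) stop("no vegetated basic state exists at this amplitude")

  # forcing wave: either the configured period, or a scanned wavenumber at
  # the (inherited) basic-state depth
  if (is.null(config$kappa_forcing)) {
    kap <- if (is.null(config$basic_state)) bs$kappa
           else solve_dispersion(wp$T, bs$H0, wp$g)$kappa
    sigma <- 2 * pi / wp$T
  } else {
    kap <- config$kappa_forcing
    sigma <- sqrt(wp$g * kap * tanh(kap * bs$H0))
  }
  T_forcing <- 2 * pi / sigma
  lam <- 2 * pi / kap
  H0 <- bs$H0
  U_b0 <- sigma * wp$a / sinh(kap * H0)

  grid <- if (!is.null(config$grid)) config$grid
          else sim_grid(lam, config$n_lambda_interior, config$n_lambda_sponge,
                        config$nodes_per_lambda)
  gam <- build_sponge(grid, config$gamma_max, config$sponge_exponent)
  nx <- grid$nx
  interior <- grid$interior

  # initial seagrass perturbation
  if (is.null(config$n1_init)) {
    n1 <- generate_initial_noise(grid, config$init_noise_rel * bs$n0,
                                 config$seed)
  } else {
    if (length(config$n1_init) != nx)
      stop("'n1_init' length does not match the grid")
    n1 <- config$n1_init
  }
  n1_initial <- n1

  dt <- config$dt_frac * T_forcing
  steps_per_period <- round(1 / config$dt_frac)

  # precomputed spectral operators
  kvec <- grid$kvec
  ka <- abs(kvec)
  th <- tanh(ka * H0)
  sch <- .sech(ka * H0)
  ktanh <- ka * th
  tanh_over_k <- ifelse(ka == 0, H0, th / pmax(ka, .Machine$double.xmin))
  ik <- 1i * kvec; ik[nx / 2 + 1] <- 0
  kx <- kap * grid$x
  g <- wp$g
  s <- sp$s

  ffwd <- function(z) stats::fft(z)
  finv <- function(z) Re(stats::fft(z, inverse = TRUE)) / nx

  # internal switches for term-attribution experiments (default: full model)
  use_dndt <- !isTRUE(config$.no_bed_motion_term)
  use_flux <- !isTRUE(config$.no_bed_flux_term)

  rhs <- function(t, phis, eta, n1, dn1dt) {
    u0b_t <- U_b0 * cos(kx - sigma * t)
    wb <- (if (use_dndt) s * dn1dt else 0) +
      (if (use_flux) finv(ik * ffwd(s * n1 * u0b_t)) else 0)
    ws <- finv(ktanh * ffwd(phis) + sch * ffwd(wb))
    list(dphis = -g * eta - gam * phis,
         deta = ws - gam * eta)
  }

  bottom_velocity <- function(t, phis, n1, dn1dt) {
    u0b_t <- U_b0 * cos(kx - sigma * t)
    wb <- (if (use_dndt) s * dn1dt else 0) +
      (if (use_flux) finv(ik * ffwd(s * n1 * u0b_t)) else 0)
    phib_hat <- sch * ffwd(phis) - tanh_over_k * ffwd(wb)
    list(u1b = finv(ik * phib_hat), u0b = u0b_t)
  }

  # trailing one-period circular buffer of u0b*u1b products
  nbuf <- steps_per_period
  buf <- matrix(0, nrow = nbuf, ncol = nx)
  buf_sum <- numeric(nx)
  buf_pos <- 0L
  buf_filled <- FALSE

  phis <- if (is.null(config$phis1_init)) numeric(nx) else config$phis1_init
  eta <- if (is.null(config$eta1_init)) numeric(nx) else config$eta1_init
  dn1dt <- numeric(nx)
  tau_b1 <- numeric(nx)
  rf <- wp$rho * wp$f_w

  step_hydro <- function(t) {
    k1 <- rhs(t, phis, eta, n1, dn1dt)
    k2 <- rhs(t + dt / 2, phis + dt / 2 * k1$dphis, eta + dt / 2 * k1$deta, n1, dn1dt)
    k3 <- rhs(t + dt / 2, phis + dt / 2 * k2$dphis, eta + dt / 2 * k2$deta, n1, dn1dt)
    k4 <- rhs(t + dt, phis + dt * k3$dphis, eta + dt * k3$deta, n1, dn1dt)
    phis <<- phis + dt / 6 * (k1$dphis + 2 * k2$dphis + 2 * k3$dphis + k4$dphis)
    eta <<- eta + dt / 6 * (k1$deta + 2 * k2$deta + 2 * k3$deta + k4$deta)
  }

  push_stress <- function(t) {
    bv <- bottom_velocity(t, phis, n1, dn1dt)
    p <- bv$u0b * bv$u1b
    buf_pos <<- (buf_pos %% nbuf) + 1L
    buf_sum <<- buf_sum - buf[buf_pos, ] + p
    buf[buf_pos, ] <<- p
    if (buf_pos == nbuf) buf_filled <<- TRUE
    tau_b1 <<- 2 * rf * buf_sum / nbuf
  }

  # ---- spin-up: hydrodynamics only over the initial topography ----
  t <- -config$spinup_periods * T_forcing
  n_spin <- config$spinup_periods * steps_per_period
  for (i in seq_len(n_spin)) {
    step_hydro(t)
    t <- t + dt
    push_stress(t)
  }

  # ---- main loop ----
  probe <- NULL
  if (!is.null(config$probe_node)) {
    probe <- matrix(NA_real_, nrow = config$n_periods * steps_per_period,
                    ncol = 2, dimnames = list(NULL, c("t", "eta1")))
    probe_i <- 0L
  }
  env_node <- abs(eta)
  period_max <- numeric(0)
  snapshots <- if (config$store_snapshots) list() else NULL
  equilibrated <- FALSE
  eta1_envelope <- NULL
  M <- config$morph_accel
  interior_frac_floor <- 0.1
  period <- 0L

  while (period < config$n_periods) {
    period <- period + 1L
    env_node <- numeric(nx)
    for (i in seq_len(steps_per_period)) {
      step_hydro(t)
      t <- t + dt
      push_stress(t)
      if (!config$topography_frozen) {
        if (!buf_filled)
          stop("stress buffer not filled: increase 'spinup_periods'")
        d <- .seagrass_rhs(n1, tau_b1, bs, sp, grid)
        n1_new <- n1 + M * dt * d
        # total density stays nonnegative
        clip <- n1_new < -bs$n0
        if (any(clip)) {
          n1_new[clip] <- -bs$n0
          if (mean(clip[interior]) > interior_frac_floor)
            warning("n1 clipped at -n0 over >10% of the interior: linearization strained")
        }
        dn1dt <- (n1_new - n1) / dt
        n1 <- n1_new
      }
      env_node <- pmax(env_node, abs(eta))
      if (!is.null(probe)) {
        probe_i <- probe_i + 1L
        probe[probe_i, ] <- c(t, eta[config$probe_node])
      }
    }
    pm <- max(env_node[interior]) / if (wp$a > 0) wp$a else 1
    if (!is.finite(pm))
      stop(sprintf("non-finite wave field at period %d (t = %.1f s)", period, t))
    if (length(period_max) > 0 && pm > 10 * max(period_max[length(period_max)], 1e-300) &&
        config$topography_frozen && pm > 1e3)
      stop(sprintf("wave field growing >10x per period at period %d: reduce dt", period))
    period_max <- c(period_max, pm)
    if (config$store_snapshots)
      snapshots[[period]] <- list(eta1 = eta, n1 = n1, tau_b1 = tau_b1, t = t)
    if (config$stop_on_equilibrium && length(period_max) >= 6) {
      recent <- utils::tail(period_max, 6)
      drift <- abs(diff(recent)) / pmax(utils::tail(recent, 5), 1e-300)
      if (all(drift < config$drift_tol)) { equilibrated <- TRUE; break }
    }
  }
  eta1_envelope <- env_node

  structure(list(config = config, basic_state = bs, grid = grid, gamma = gam,
                 kappa = kap, sigma = sigma, T_forcing = T_forcing, lam = lam,
                 eta1 = eta, phis1 = phis, n1 = n1, tau_b1 = tau_b1,
                 n1_initial = n1_initial, period_max_eta1 = period_max,
                 eta1_envelope = eta1_envelope, equilibrated = equilibrated,
                 n_periods_run = period, t_end = t, snapshots = snapshots,
                 probe = if (!is.null(probe)) probe[seq_len(probe_i), , drop = FALSE]),
            class = "sim_result")
}

#' Trailing-period-averaged bed shear stress perturbation
#'
#' Leading-order perturbation of the time-averaged bed shear stress when the
#' bottom velocity is `u0b + u1b`: from \eqn{\tau_b = \rho f_w \langle u^2
#' \rangle} (the quadratic friction law with the orbital-velocity average
#' taken over one trailing forcing period),
#' \deqn{\tau_{b1} = 2 \rho f_w \langle u_{0b}\, u_{1b} \rangle.}
#'
#' @param u0b_hist matrix (time steps x nodes) of basic-state bottom
#'   velocities over one full forcing period \[m/s\]
#' @param u1b_hist matrix of perturbation bottom velocities, same shape
#' @param rho water density \[kg/m^3\]
#' @param f_w wave friction factor
#' @return per-node stress perturbation \[Pa\]
#' @export
averaged_shear_perturbation <- function(u0b_hist, u1b_hist, rho = 1025, f_w = 0.05) {
  if (!is.matrix(u0b_hist) || !is.matrix(u1b_hist) ||
      !all(dim(u0b_hist) == dim(u1b_hist)))
    stop("'u0b_hist' and 'u1b_hist' must be matrices of equal shape")
  if (nrow(u0b_hist) < 2)
    stop("insufficient history: need at least one full period of samples")
  2 * rho * f_w * colMeans(u0b_hist * u1b_hist)
}

#' Seagrass perturbation tendency
#'
#' Right-hand side of the perturbation density equation: the full density
#' equation evaluated at `n0 + n1` with mortality `omega0 + omega_c * tau_b1`,
#' minus the basic-state balance. The nonlinear facilitation and competition
#' terms are retained so that growth can saturate:
#' \deqn{\partial_t n_1 = -\omega_0 n_1 - \omega_c \tau_{b1} (n_0 + n_1)
#'   + \alpha (2 n_0 n_1 + n_1^2) - \beta (3 n_0^2 n_1 + 3 n_0 n_1^2 + n_1^3)
#'   + \delta \partial_{xx} n_1.}
#' Rates are biological; coupled runs scale this by the morphological
#' acceleration factor.
#'
#' @param n1 density perturbation per node
#' @param tau_b1 bed shear stress perturbation per node \[Pa\]
#' @param bs [uniform_equilibrium()] basic state (supplies `n0`, `omega0`)
#' @param sp [seagrass_params()]
#' @param grid [sim_grid()] (spectral second derivative)
#' @return tendency `dn1/dt` per node \[1/s\]
#' @export
seagrass_tendency <- function(n1, tau_b1, bs, sp, grid) {
  .seagrass_rhs(n1, tau_b1, bs, sp, grid)
}

#' Canonical pattern-formation study configuration
#'
#' The package's reference conditions for the coupled pattern-forming run: an
#' 8-s forcing wave over a 10-m bare bed with the default seagrass
#' parameters, forcing amplitude set as a fraction of the transcritical
#' amplitude `a*`, a 20-wavelength interior with 2-wavelength sponges, 64
#' nodes per wavelength, `dt = T/128` and morphological acceleration 1000.
#' The default `a_rel = 0.96` sits inside the modulation-instability window
#' (between `a_MI` and `a*`), where the meadow develops a pattern at half
#' the forcing wavelength within 25 forcing periods.
#'
#' @param a_rel forcing amplitude as a fraction of `a*`
#' @param T forcing period \[s\]
#' @param sp [seagrass_params()]
#' @param seed noise seed
#' @param ... further arguments passed to [sim_config()]
#' @return [sim_config()] object (attribute `a_star` records `a*`)
#' @export
#' @examples
#' cfg <- default_pattern_config(seed = 1)
#' cfg$wp$a / attr(cfg, "a_star")
default_pattern_config <- function(a_rel = 0.96, T = 8, sp = seagrass_params(),
                                   seed = 0, ...) {
  a_star <- critical_amplitude(T, wave_parameters(T = T), sp)
  wp <- wave_parameters(a = a_rel * a_star, T = T)
  cfg <- sim_config(wp = wp, sp = sp, seed = seed, ...)
  attr(cfg, "a_star") <- a_star
  cfg
}
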