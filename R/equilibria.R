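#' Seagrass growth, mortality and topography parameters
#'
#' Parameters of the seagrass density equation
#' \deqn{\partial_t n = -\omega n + \alpha n^2 - \beta n^3 + \delta \partial_{xx} n}
#' with stress-dependent net mortality \eqn{\omega = \omega_b + \omega_c \tau_b},
#' and of the linear density-to-topography map \eqn{H = h - s\,n}.
#'
#' Rates are slow (biological) rates in \[1/s\]; in coupled simulations the
#' seagrass equation is additionally scaled by a morphological acceleration
#' factor (see [sim_config()]), the standard device for bridging the gap
#' between wave and meadow time scales.
#'
#' The defaults put the meadow in the regime the package's simulations
#' explore: a stable homogeneous meadow in calm water (`omega_b < 0`), unit
#' equilibrium density at zero forcing (`n0 = 1`), a 2-m matte at that calm
#' density (`s = 2`; at the pattern-forming states the uniform matte is a few
#' decimetres and its modulations far smaller), and a stress coupling giving
#' a transcritical wave amplitude `a* ~ 0.5` m for an 8-s wave over a 10-m
#' bare bed. Facilitation is weak relative to competition, so the meadow's
#' local (non-spatial) recovery rate shrinks as forcing approaches `a*`;
#' this is what lets the reflection feedback destabilize the uniform meadow
#' into patterns in a window just below `a*`.
#'
#' @param omega_b background net mortality rate \[1/s\]; negative = net growth
#' @param omega_c stress-mortality coupling \[1/(s Pa)\]
#' @param alpha facilitation coefficient \[1/(s density)\]
#' @param beta competition coefficient \[1/(s density^2)\]
#' @param delta lateral dispersion coefficient \[m^2/s\]
#' @param s topography coefficient \[m per unit density\]
#' @param h bare-bed water depth \[m\]
#' @return object of class `seagrass_params`
#' @export
seagrass_params <- function(omega_b = -1e-4, omega_c = 2.5e-5,
                            alpha = 5e-6, beta = 1.05e-4,
                            delta = 1e-4, s = 2, h = 10) {
  if (beta <= 0) stop("'beta' must be > 0")
  if (delta < 0 || s < 0) stop("'delta' and 's' must be >= 0")
  if (h <= 0) stop("bare-bed depth 'h' must be > 0")
  if (omega_b >= 0)
    stop("'omega_b' must be < 0 (net growth in calm water)")
  structure(list(omega_b = omega_b, omega_c = omega_c, alpha = alpha,
                 beta = beta, delta = delta, s = s, h = h),
            class = "seagrass_params")
}

# largest nonnegative root of  -omega0*n + alpha*n^2 - beta*n^3 = 0, n > 0
# i.e. beta*n^2 - alpha*n + omega0 = 0; NA if no nonnegative root exists
.largest_density_root <- function(omega0, alpha, beta) {
  disc <- alpha^2 - 4 * beta * omega0
  if (disc < 0) return(NA_real_)
  n <- (alpha + sqrt(disc)) / (2 * beta)
  if (n < 0) NA_real_ else n
}

#' Spatially uniform basic state of the wave-seagrass model
#'
#' Solves the uniform equilibrium at forcing amplitude `a`. On the `bare`
#' branch the density is zero and the wave quantities are evaluated at the
#' bare-bed depth `h`. On the `vegetated` branch the equilibrium is
#' self-consistent: the meadow raises the bed (`H0 = h - s n0`), which
#' shortens the wave and raises the near-bed stress, which feeds back on the
#' equilibrium density. The equilibrium is the zero of the per-capita net
#' growth rate \eqn{R(n) = -\omega(\tau_{b0}(n, a)) + \alpha n - \beta n^2},
#' found by bracketed root-finding between the bare state and the calm-water
#' density (tolerance `1e-12` on `n0`): this follows the vegetated branch
#' continuously down to zero density at the transcritical point.
#'
#' @param a forcing wave amplitude \[m\]
#' @param T forcing wave period \[s\]
#' @param wp [wave_parameters()] (supplies `g`, `rho`, `f_w`; its `a`, `T`
#'   are ignored in favour of the arguments)
#' @param sp [seagrass_params()]
#' @param branch `"vegetated"` or `"bare"`
#' @return list of class `basic_state`: `a`, `n0`, `H0`, `kappa`, `sigma`,
#'   `U_b0`, `tau_b0`, `omega0` (net mortality at the state), `branch`,
#'   `exists` (`FALSE` with `n0 = NA` if no nonnegative vegetated root exists
#'   at this amplitude)
#' @export
uniform_equilibrium <- function(a, T, wp = wave_parameters(), sp = seagrass_params(),
                                branch = c("vegetated", "bare")) {
  branch <- match.arg(branch)
  if (a < 0) stop("'a' must be >= 0")
  g <- wp$g; rho <- wp$rho; f_w <- wp$f_w
  sigma <- 2 * pi / T

  state_at <- function(n0) {
    H0 <- sp$h - sp$s * n0
    if (H0 <= 0)
      stop("model-validity error: meadow topography reaches the water surface (H0 <= 0)")
    kap <- solve_dispersion(T, H0, g)$kappa
    U_b0 <- if (a > 0) sigma * a / sinh(kap * H0) else 0
    tau_b0 <- 0.5 * rho * f_w * U_b0^2
    list(n0 = n0, H0 = H0, kappa = kap, U_b0 = U_b0, tau_b0 = tau_b0,
         omega0 = sp$omega_b + sp$omega_c * tau_b0)
  }

  if (branch == "bare") {
    st <- state_at(0)
    return(structure(c(st, list(a = a, sigma = sigma, branch = "bare",
                                exists = TRUE)),
                     class = "basic_state"))
  }

  # vegetated: root of the per-capita net growth rate R(n), bracketed between
  # the bare state and the calm-water density
  percap <- function(n) {
    st <- state_at(n)
    -st$omega0 + sp$alpha * n - sp$beta * n^2
  }
  n_calm <- .largest_density_root(sp$omega_b, sp$alpha, sp$beta)
  r0 <- percap(0)
  if (r0 <= 0) {
    # bare state not invadable: no vegetated equilibrium connected to it
    st <- state_at(0)
    return(structure(c(st, list(a = a, sigma = sigma, branch = "vegetated",
                                exists = FALSE)),
                     class = "basic_state"))
  }
  if (a == 0) {
    n0 <- n_calm
  } else {
    # percap(n_calm) <= 0 since any wave stress only adds mortality
    n0 <- stats::uniroot(percap, lower = 0, upper = n_calm, tol = 1e-12)$root
  }
  st <- state_at(n0)
  resid <- -st$omega0 * n0 + sp$alpha * n0^2 - sp$beta * n0^3
  scale <- max(abs(sp$omega_b) * max(n0, 1), 1e-300)
  if (abs(resid) / scale > 1e-8)
    stop(sprintf("uniform steady-state residual %.2e above tolerance", resid))
  structure(c(st, list(a = a, sigma = sigma, branch = "vegetated",
                       exists = n0 >= 0)),
            class = "basic_state")
}

#' Transcritical forcing amplitude of the bare state
#'
#' Closed form for the amplitude `a*` at which the net mortality of the bare
#' state vanishes, \eqn{\omega(a^*, n_0 = 0) = 0}:
#' \deqn{a^* = \frac{\sinh(\kappa_h h)}{\sigma}
#'   \sqrt{\frac{-2 \omega_b}{\rho f_w \omega_c}}}
#' with \eqn{\kappa_h} the wavenumber at the bare-bed depth. For `a < a*` the
#' bare state is unstable to homogeneous perturbations (vegetation invades);
#' for `a > a*` it is stable. `a*` scales as \eqn{\omega_c^{-1/2}}.
#'
#' @inheritParams uniform_equilibrium
#' @return critical amplitude `a*` \[m\]
#' @export
critical_amplitude <- function(T, wp = wave_parameters(), sp = seagrass_params()) {
  if (sp$omega_c <= 0) stop("'omega_c' must be > 0 for a bifurcation to exist")
  if (sp$omega_b >= 0) stop("no bifurcation: 'omega_b' must be < 0")
  sigma <- 2 * pi / T
  kap_h <- solve_dispersion(T, sp$h, wp$g)$kappa
  sinh(kap_h * sp$h) / sigma * sqrt(-2 * sp$omega_b / (wp$rho * wp$f_w * sp$omega_c))
}

#' Growth rate of homogeneous perturbations on the bare state
#'
#' A uniform infinitesimal vegetation perturbation on the bare state grows at
#' rate \eqn{-\omega(a, n_0 = 0)}: positive below the transcritical amplitude
#' `a*`, zero at `a*`, negative above.
#'
#' @inheritParams uniform_equilibrium
#' @return growth rate \[1/s\]
#' @export
homogeneous_stability <- function(a, T, wp = wave_parameters(), sp = seagrass_params()) {
  st <- uniform_equilibrium(a, T, wp, sp, branch = "bare")
  -st$omega0
}

#' Bifurcation diagram of the uniform states
#'
#' Evaluates both uniform branches over a grid of forcing amplitudes.
#'
#' @param a_grid forcing amplitudes \[m\]
#' @inheritParams uniform_equilibrium
#' @return data frame with columns `a`, `a_rel` (`a/a*`), `n0_veg`, `n0_bare`,
#'   `kappa_veg`, `kappa_bare`, `tau_b0_veg`, `tau_b0_bare`; vegetated entries
#'   are `NA` where no vegetated equilibrium exists
#' @export
bifurcation_diagram <- function(a_grid, T, wp = wave_parameters(),
                                sp = seagrass_params()) {
  a_star <- critical_amplitude(T, wp, sp)
  rows <- lapply(a_grid, function(a) {
    veg <- uniform_equilibrium(a, T, wp, sp, "vegetated")
    bare <- uniform_equilibrium(a, T, wp, sp, "bare")
    data.frame(a = a, a_rel = a / a_star,
               n0_veg = if (veg$exists) veg$n0 else NA_real_,
               n0_bare = bare$n0,
               kappa_veg = if (veg$exists) veg$kappa else NA_real_,
               kappa_bare = bare$kappa,
               tau_b0_veg = if (veg$exists) veg$tau_b0 else NA_real_,
               tau_b0_bare = bare$tau_b0)
  })
  out <- do.call(rbind, rows)
  attr(out, "a_star") <- a_star
  out
}
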