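#' Physical wave and fluid parameters
#'
#' Bundles the constants of the linear-wave and bed-shear-stress closures:
#' forcing amplitude and period, gravitational acceleration, water density and
#' the (constant) wave friction factor entering the quadratic stress law
#' \eqn{\tau_b = \tfrac12 \rho f_w U_b^2}.
#'
#' @param a wave amplitude \[m\] (half the wave height)
#' @param T wave period \[s\]
#' @param g gravitational acceleration \[m/s^2\]
#' @param rho water density \[kg/m^3\] (seawater default)
#' @param f_w dimensionless wave friction factor
#' @return object of class `wave_parameters` with fields `a`, `T`, `sigma`
#'   (angular frequency `2*pi/T`), `g`, `rho`, `f_w`
#' @export
#' @examples
#' wp <- wave_parameters(a = 0.25, T = 8)
#' wp$sigma * wp$T / (2 * pi)  # 1 by construction
wave_parameters <- function(a = 0.25, T = 8, g = 9.81, rho = 1025, f_w = 0.05) {
  if (!is.numeric(a) || a < 0) stop("wave amplitude 'a' must be >= 0")
  if (!is.numeric(T) || T <= 0) stop("wave period 'T' must be > 0")
  if (g <= 0 || rho <= 0 || f_w <= 0) stop("'g', 'rho' and 'f_w' must be > 0")
  structure(list(a = a, T = T, sigma = 2 * pi / T, g = g, rho = rho, f_w = f_w),
            class = "wave_parameters")
}

#' Solve the linear dispersion relation
#'
#' Finds the unique positive wavenumber \eqn{\kappa} satisfying
#' \eqn{\sigma^2 = g \kappa \tanh(\kappa H)} for a wave of period `T` in water
#' of depth `H`, by Brent root-finding on a bracket that always contains the
#' root (the deep-water wavenumber \eqn{\sigma^2/g} is a lower bound and
#' \eqn{\sigma^2/(g \tanh(\sigma^2 H / g))} an upper bound).
#'
#' @param T wave period \[s\]
#' @param H water depth \[m\]
#' @param g gravitational acceleration \[m/s^2\]
#' @return list of class `dispersion_solution`: `kappa` \[rad/m\], `lam`
#'   wavelength \[m\], `H`, `sigma`, `regime` (one of `"deep"`,
#'   `"intermediate"`, `"shallow"` by the conventional `kappa*H` cut-offs
#'   `pi` and `pi/10`), and the relative residual of the dispersion relation.
#' @export
#' @examples
#' solve_dispersion(T = 10, H = 94)$lam  # ~156 m, nearly deep water
solve_dispersion <- function(T, H, g = 9.81) {
  if (!is.numeric(T) || T <= 0) stop("wave period 'T' must be > 0")
  if (!is.numeric(H) || H <= 0) stop("water depth 'H' must be > 0")
  sigma <- 2 * pi / T
  k_deep <- sigma^2 / g  # tanh <= 1  => kappa >= k_deep
  # kappa >= k_deep  =>  tanh(kappa H) >= tanh(k_deep H)
  #                  =>  kappa = sigma^2/(g tanh(kappa H)) <= k_deep/tanh(k_deep H)
  lo <- k_deep * (1 - 1e-12)
  hi <- k_deep / tanh(k_deep * H) * (1 + 1e-9)
  f <- function(k) g * k * tanh(k * H) - sigma^2
  root <- tryCatch(
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14 * max(1, k_deep)),
    error = function(e) stop(sprintf(
      "dispersion root not bracketed in [%g, %g]: %s", lo, hi, conditionMessage(e)))
  )
  kappa <- root$root
  res <- abs(sigma^2 - g * kappa * tanh(kappa * H)) / sigma^2
  if (res > 1e-10)
    stop(sprintf("dispersion residual %.3e above tolerance in [%g, %g]", res, lo, hi))
  kH <- kappa * H
  regime <- if (kH > pi) "deep" else if (kH < pi / 10) "shallow" else "intermediate"
  structure(list(kappa = kappa, lam = 2 * pi / kappa, H = H, sigma = sigma,
                 regime = regime, residual = res),
            class = "dispersion_solution")
}

#' Deep-water wavelength of a wave of period T
#'
#' \eqn{\lambda_\infty = g T^2 / (2\pi)}, the limit of the dispersion relation
#' for \eqn{\kappa H \gg 1}.
#'
#' @inheritParams solve_dispersion
#' @return deep-water wavelength \[m\]
#' @export
deep_water_wavelength <- function(T, g = 9.81) {
  if (!is.numeric(T) || any(T < 0)) stop("wave period 'T' must be >= 0")
  g * T^2 / (2 * pi)
}

#' Shoal a deep-water wavelength to finite depth
#'
#' Solves the depth-limited wavelength \eqn{\lambda} from the stationary-wave
#' form of the dispersion relation,
#' \eqn{\lambda = \lambda_\infty \tanh(2 \pi H / \lambda)}: the period is
#' conserved as the wave propagates shoreward, so the wavelength shortens with
#' decreasing depth. Solved by damped fixed-point iteration, polished with a
#' bisection fallback; converged to `|dlam| < 1e-8` m.
#'
#' @param lam_inf deep-water wavelength \[m\]
#' @param H water depth \[m\] (vectorized)
#' @return wavelength at depth `H` \[m\]
#' @export
#' @examples
#' shoal_wavelength(180, c(2, 7))   # ~47 and ~85 m
#' shoal_wavelength(168, c(7, 25))  # ~82 and ~137 m
shoal_wavelength <- function(lam_inf, H) {
  if (!is.numeric(lam_inf) || lam_inf <= 0) stop("'lam_inf' must be > 0")
  if (!is.numeric(H) || any(H <= 0)) stop("depth 'H' must be > 0")
  vapply(H, function(h) {
    f <- function(lam) lam_inf * tanh(2 * pi * h / lam) - lam
    # f(eps) > 0 and f(lam_inf) <= 0: root bracketed in (0, lam_inf]
    lam <- stats::uniroot(f, lower = 1e-10, upper = lam_inf * (1 + 1e-12),
                          tol = 1e-12)$root
    if (abs(f(lam)) > 1e-8)
      stop(sprintf("shoaling iteration failed to converge at H = %g m", h))
    lam
  }, numeric(1))
}

#' Near-bed orbital kinematics and time-averaged bed shear stress
#'
#' For a wave of significant height `Hs` and period `T` over depth `H`:
#' orbital excursion amplitude at the bed \eqn{A_b = H_s / (2 \sinh(\kappa H))},
#' orbital velocity amplitude \eqn{U_b = 2 \pi A_b / T}, and time-averaged bed
#' shear stress \eqn{\tau_b = \tfrac12 \rho f_w U_b^2}.
#'
#' @param Hs significant wave height \[m\]
#' @param T wave period \[s\]
#' @param kappa wavenumber \[rad/m\]; must solve the dispersion relation for
#'   `(T, H)` (checked)
#' @param H water depth \[m\]
#' @param rho water density \[kg/m^3\]
#' @param f_w wave friction factor
#' @param g gravitational acceleration \[m/s^2\]
#' @return list `A_b` \[m\], `U_b` \[m/s\], `tau_b` \[Pa\]
#' @export
#' @examples
#' ds <- solve_dispersion(T = 10, H = 94)
#' bottom_kinematics(Hs = 8, T = 10, kappa = ds$kappa, H = 94)
bottom_kinematics <- function(Hs, T, kappa, H, rho = 1025, f_w = 0.05, g = 9.81) {
  if (!is.numeric(Hs) || any(Hs < 0)) stop("'Hs' must be >= 0")
  sigma <- 2 * pi / T
  res <- abs(sigma^2 - g * kappa * tanh(kappa * H)) / sigma^2
  if (res > 1e-8)
    stop(sprintf("(kappa, H, T) inconsistent with the dispersion relation (residual %.2e)", res))
  A_b <- Hs / (2 * sinh(kappa * H))
  U_b <- 2 * pi * A_b / T
  tau_b <- 0.5 * rho * f_w * U_b^2
  list(A_b = A_b, U_b = U_b, tau_b = tau_b)
}

#' Analytic basic-state wave fields of a linear gravity wave
#'
#' Surface elevation, velocity potential and velocity components of a
#' monochromatic linear gravity wave of amplitude `a` over a flat bed at
#' depth `H0`:
#' \deqn{\eta_0 = a \cos(\kappa x - \sigma t)}
#' \deqn{\phi_0 = \frac{\sigma a}{\kappa}
#'   \frac{\cosh[\kappa (z + H_0)]}{\sinh(\kappa H_0)} \sin(\kappa x - \sigma t)}
#' with \eqn{u_0 = \partial_x \phi_0}, \eqn{w_0 = \partial_z \phi_0} evaluated
#' analytically; `w0` vanishes identically at the bed.
#'
#' @param wp [wave_parameters()] object (supplies `a`, `sigma`, `g`)
#' @param ds [solve_dispersion()] solution at depth `H0` (supplies `kappa`)
#' @param H0 water depth \[m\]
#' @param x horizontal position(s) \[m\]
#' @param z vertical position(s) \[m\], `-H0 <= z <= 0`
#' @param t time \[s\]
#' @return list of fields `eta0`, `phi0`, `u0`, `w0` evaluated at `(x, z, t)`
#' @export
basic_wave_fields <- function(wp, ds, H0, x, z, t) {
  if (any(z < -H0 - 1e-12) || any(z > 1e-12))
    stop("'z' must lie in the water column [-H0, 0]")
  kap <- ds$kappa; sig <- wp$sigma; a <- wp$a
  ph <- kap * x - sig * t
  shk <- sinh(kap * H0)
  czh <- cosh(kap * (z + H0))
  szh <- sinh(kap * (z + H0))
  list(
    eta0 = a * cos(ph),
    phi0 = (sig * a / kap) * czh / shk * sin(ph),
    u0   = sig * a * czh / shk * cos(ph),
    w0   = sig * a * szh / shk * sin(ph)
  )
}
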