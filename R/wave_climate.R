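#' Construct a wave-climate series
#'
#' A wave climate is an ordered record of sea states at a fixed offshore
#' point: timestamps, significant wave height `Hs` and peak period `Tp`.
#'
#' @param time timestamps (`POSIXct` or anything ordered); strictly increasing
#' @param hs_m significant wave heights \[m\], `>= 0`
#' @param tp_s peak wave periods \[s\], `> 0`
#' @param site_depth water depth at the climate point \[m\]
#' @param site_label free-text site name
#' @return data frame of class `wave_climate` with attributes `site_depth`,
#'   `site_label`
#' @export
wave_climate <- function(time, hs_m, tp_s, site_depth, site_label = "") {
  n <- length(time)
  if (length(hs_m) != n || length(tp_s) != n)
    stop("'time', 'hs_m' and 'tp_s' must have equal length")
  if (n == 0) stop("empty wave-climate series")
  bad <- which(!is.finite(hs_m) | hs_m < 0 | !is.finite(tp_s) | tp_s <= 0)
  if (length(bad))
    stop("invalid records (need Hs >= 0 and Tp > 0) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.unsorted(time, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(site_depth) || site_depth <= 0)
    stop("'site_depth' must be > 0")
  out <- data.frame(time = time, hs_m = hs_m, tp_s = tp_s)
  attr(out, "site_depth") <- site_depth
  attr(out, "site_label") <- site_label
  class(out) <- c("wave_climate", "data.frame")
  out
}

#' Derive per-record wave quantities at the climate point
#'
#' Augments each `(Hs, Tp)` record with wavenumber and wavelength from the
#' dispersion relation at the site depth, near-bed orbital velocity `U_b` and
#' time-averaged bed shear stress `tau_b` from the quadratic friction law.
#'
#' @param series [wave_climate()] object
#' @param rho water density \[kg/m^3\]
#' @param f_w wave friction factor
#' @param g gravitational acceleration \[m/s^2\]
#' @return the series with added columns `kappa`, `lam`, `U_b`, `tau_b`
#' @export
derive_wave_quantities <- function(series, rho = 1025, f_w = 0.05, g = 9.81) {
  stopifnot(inherits(series, "wave_climate"))
  H <- attr(series, "site_depth")
  # dispersion depends on Tp only: solve once per unique period
  uT <- unique(series$tp_s)
  kap_u <- vapply(uT, function(T) solve_dispersion(T, H, g)$kappa, numeric(1))
  kappa <- kap_u[match(series$tp_s, uT)]
  A_b <- series$hs_m / (2 * sinh(kappa * H))
  U_b <- 2 * pi * A_b / series$tp_s
  series$kappa <- kappa
  series$lam <- 2 * pi / kappa
  series$U_b <- U_b
  series$tau_b <- 0.5 * rho * f_w * U_b^2
  series
}

#' Select the most energetic records by bed shear stress
#'
#' Keeps the records whose bed shear stress is at or above the `q` empirical
#' quantile (type-7, linear interpolation) of the `tau_b` distribution; ties
#' at the threshold are retained.
#'
#' @param series output of [derive_wave_quantities()]
#' @param q quantile in (0, 1); the most energetic `1 - q` fraction is kept
#' @return subset of `series` (class `energetic_subset`), with attributes
#'   `quantile`, `threshold` and `fraction` (retained fraction)
#' @export
select_energetic <- function(series, q = 0.99) {
  stopifnot(inherits(series, "wave_climate"))
  if (is.null(series$tau_b))
    stop("run derive_wave_quantities() first")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  if (nrow(series) == 0) stop("empty series")
  thr <- stats::quantile(series$tau_b, probs = q, type = 7, names = FALSE)
  keep <- series$tau_b >= thr
  out <- series[keep, , drop = FALSE]
  attr(out, "site_depth") <- attr(series, "site_depth")
  attr(out, "site_label") <- attr(series, "site_label")
  attr(out, "quantile") <- q
  attr(out, "threshold") <- thr
  attr(out, "fraction") <- mean(keep)
  class(out) <- c("energetic_subset", class(series))
  out
}

#' Wavelength-versus-depth envelope of the energetic wave subset
#'
#' Each retained record is assigned its deep-water wavelength
#' \eqn{\lambda_\infty = g T_p^2/(2\pi)} and shoaled to every depth of the
#' grid with [shoal_wavelength()]; per depth, the 2.5, 50 and 97.5 percent
#' quantiles of the resulting wavelength distribution form the envelope.
#'
#' @param subset output of [select_energetic()] (or any derived series)
#' @param depths depth grid \[m\], default 1 to 30 m in 0.25 m steps
#' @param g gravitational acceleration \[m/s^2\]
#' @return data frame of class `depth_envelope`: `depth_m`, `q025`, `q50`,
#'   `q975` \[m\]
#' @export
depth_envelope <- function(subset, depths = seq(1, 30, by = 0.25), g = 9.81) {
  if (nrow(subset) == 0) stop("empty energetic subset")
  if (any(depths <= 0)) stop("depths must be positive")
  lam_inf <- deep_water_wavelength(subset$tp_s, g)
  u_lam <- unique(lam_inf)
  # shoaling is monotone in lam_inf, so quantiles commute with shoaling;
  # still computed per record for clarity, deduplicated by unique lam_inf
  shoaled <- vapply(u_lam, function(li) shoal_wavelength(li, depths),
                    numeric(length(depths)))
  shoaled <- matrix(shoaled, nrow = length(depths))
  full <- shoaled[, match(lam_inf, u_lam), drop = FALSE]
  qs <- t(apply(full, 1, stats::quantile,
                probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE))
  out <- data.frame(depth_m = depths, q025 = qs[, 1], q50 = qs[, 2], q975 = qs[, 3])
  class(out) <- c("depth_envelope", "data.frame")
  out
}

#' Compare seagrass pattern observations with the wave envelope
#'
#' The Bragg condition predicts seagrass pattern wavelengths of half the
#' forcing water wavelength, so *twice* each observed pattern wavelength is
#' compared against the wavelength envelope at its depth (envelope curves are
#' linearly interpolated between grid depths).
#'
#' @param env [depth_envelope()] result
#' @param obs data frame with columns `depth_m`, `pattern_wavelength_m`
#'   (and optionally `site`)
#' @return data frame `depth_m`, `lam2_obs` (doubled pattern wavelength),
#'   `q025`, `q50`, `q975`, `inside` (flag), `ratio` (`lam2_obs / q50`);
#'   attributes `fraction_inside`, `median_ratio`, `n_skipped` (observations
#'   outside the depth grid, dropped with a warning)
#' @export
compare_patterns <- function(env, obs) {
  stopifnot(is.data.frame(obs),
            all(c("depth_m", "pattern_wavelength_m") %in% names(obs)))
  rng <- range(env$depth_m)
  in_grid <- obs$depth_m >= rng[1] & obs$depth_m <= rng[2]
  n_skipped <- sum(!in_grid)
  if (n_skipped > 0)
    warning(sprintf("%d observation(s) outside the depth grid [%g, %g] m skipped",
                    n_skipped, rng[1], rng[2]))
  obs <- obs[in_grid, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations within the depth grid")
  itp <- function(y) stats::approx(env$depth_m, y, xout = obs$depth_m)$y
  q025 <- itp(env$q025); q50 <- itp(env$q50); q975 <- itp(env$q975)
  lam2 <- 2 * obs$pattern_wavelength_m
  out <- data.frame(depth_m = obs$depth_m, lam2_obs = lam2,
                    q025 = q025, q50 = q50, q975 = q975,
                    inside = lam2 >= q025 & lam2 <= q975,
                    ratio = lam2 / q50)
  if (!is.null(obs$site)) out$site <- obs$site
  attr(out, "fraction_inside") <- mean(out$inside)
  attr(out, "median_ratio") <- stats::median(out$ratio)
  attr(out, "n_skipped") <- n_skipped
  out
}
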