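# run fn with a private RNG stream; leaves the caller's RNG state untouched
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic wave-climate series
#'
#' Emulates a multi-year record of 3-hourly sea states at a fixed offshore
#' point. Peak periods are log-normal; significant wave height follows a
#' power law in the period with log-normal scatter
#' (`Hs = hs_coef * Tp^hs_exp * exp(noise)`), so the most energetic (highest
#' bed shear stress) records are the long-period swell events, mirroring how
#' storm waves dominate the stress climate. The default period distribution
#' puts the 99th percentile of `Tp` near 10.4 s, the regime of the western
#' Mediterranean reanalysis points the package's examples emulate.
#'
#' @param n_records number of records
#' @param site_depth depth at the climate point \[m\]
#' @param cadence_h record spacing \[hours\]
#' @param tp_median median peak period \[s\]
#' @param tp_sdlog log-sd of the period distribution
#' @param hs_coef,hs_exp,hs_sdlog height law `Hs = hs_coef * Tp^hs_exp *
#'   exp(N(0, hs_sdlog))`
#' @param start first timestamp (UTC)
#' @param site_label free-text label
#' @param seed integer seed; identical seeds give identical series
#' @return [wave_climate()] object
#' @export
#' @examples
#' cl <- generate_wave_climate(1000, seed = 1)
#' stats::quantile(cl$tp_s, 0.99)
generate_wave_climate <- function(n_records = 10000, site_depth = 29.7,
                                  cadence_h = 3, tp_median = 4.6,
                                  tp_sdlog = 0.35, hs_coef = 0.05,
                                  hs_exp = 2, hs_sdlog = 0.3,
                                  start = "1980-01-01", site_label = "synthetic",
                                  seed = 1) {
  if (n_records < 1) stop("'n_records' must be >= 1")
  if (tp_median <= 0 || tp_sdlog <= 0 || hs_coef <= 0 || hs_sdlog < 0)
    stop("invalid distribution parameters")
  .with_seed(seed, function() {
    tp <- stats::rlnorm(n_records, meanlog = log(tp_median), sdlog = tp_sdlog)
    hs <- hs_coef * tp^hs_exp * exp(stats::rnorm(n_records, 0, hs_sdlog))
    tm <- as.POSIXct(start, tz = "UTC") + 3600 * cadence_h * (seq_len(n_records) - 1)
    wave_climate(tm, hs, tp, site_depth = site_depth, site_label = site_label)
  })
}

#' Generate synthetic seagrass pattern observations
#'
#' Samples observation depths uniformly and places each pattern wavelength at
#' half the shoaled water wavelength for that depth, with multiplicative
#' noise: `lam_n = shoal_wavelength(lam_inf, H) / 2 * (1 + eps)`,
#' `eps ~ N(0, noise_sd)`. The half-wavelength (Bragg) relation is built in,
#' so these tables exercise the envelope-comparison pipeline end to end.
#'
#' @param n_obs number of observations
#' @param depth_range depth sampling range \[m\]
#' @param lam_inf deep-water wavelength of the forcing climate \[m\]
#' @param noise_sd relative wavelength noise (0 = exact half-wavelength)
#' @param site site label
#' @param seed integer seed
#' @return data frame `depth_m`, `pattern_wavelength_m`, `site`
#' @export
generate_pattern_observations <- function(n_obs = 100, depth_range = c(2, 25),
                                          lam_inf = 168, noise_sd = 0.1,
                                          site = "synthetic", seed = 1) {
  .with_seed(seed, function() {
    H <- stats::runif(n_obs, depth_range[1], depth_range[2])
    lam <- shoal_wavelength(lam_inf, H)
    eps <- if (noise_sd > 0) stats::rnorm(n_obs, 0, noise_sd) else numeric(n_obs)
    data.frame(depth_m = H,
               pattern_wavelength_m = lam / 2 * (1 + eps),
               site = site)
  })
}

#' Seeded white-noise initial seagrass perturbation
#'
#' Zero-mean Gaussian noise on the interior nodes, rescaled so the interior
#' root-mean-square equals `amplitude` exactly; sponge nodes are zero.
#'
#' @param grid [sim_grid()]
#' @param amplitude target interior rms
#' @param seed integer seed
#' @return noise field on the full grid
#' @export
generate_initial_noise <- function(grid, amplitude, seed) {
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  .with_seed(seed, function() {
    n1 <- numeric(grid$nx)
    z <- stats::rnorm(sum(grid$interior))
    z <- z - mean(z)
    n1[grid$interior] <- z / sqrt(mean(z^2)) * amplitude
    n1
  })
}
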