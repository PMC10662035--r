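#' Wavenumber power spectrum of the interior seagrass perturbation
#'
#' Detrends (removes the mean of) the interior segment of `n1`, applies a
#' Hann window (the masked interior segment is not periodic), and returns the
#' one-sided wavenumber power spectrum. The dominant mode excludes `k = 0`
#' and the first two resolvable bins, where window leakage from the mean and
#' envelope resides.
#'
#' @param n1 seagrass perturbation field on the full grid
#' @param grid [sim_grid()]
#' @param kappa_forcing forcing wavenumber \[rad/m\] used for the ratio
#' @return list of class `spectrum_result`: `k` bin wavenumbers \[rad/m\],
#'   `power`, `amplitude` (`sqrt(power)`), `k_dominant`, `ratio`
#'   (`k_dominant / kappa_forcing`), `dk` bin width, `no_pattern` flag for an
#'   all-zero field
#' @export
pattern_spectrum <- function(n1, grid, kappa_forcing) {
  seg <- n1[grid$interior]
  m <- length(seg)
  if (m < 8) stop("interior mask too small for a spectrum")
  if (all(seg == 0)) {
    return(structure(list(k = numeric(0), power = numeric(0),
                          amplitude = numeric(0), k_dominant = NA_real_,
                          ratio = NA_real_, dk = NA_real_, no_pattern = TRUE),
                     class = "spectrum_result"))
  }
  seg <- seg - mean(seg)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))  # Hann
  sw <- seg * w
  len <- m * grid$dx
  sp <- stats::fft(sw)
  nk <- ceiling(m / 2)  # all non-negative bins below the Nyquist frequency
  k <- 2 * pi / len * (0:(nk - 1))
  power <- (Mod(sp[1:nk]) / m)^2
  # exclude k = 0 and the first two bins (leakage) from the dominant-mode search
  search <- seq_along(k) > 3
  idx <- which(search)[which.max(power[search])]
  structure(list(k = k, power = power, amplitude = sqrt(power),
                 k_dominant = k[idx], ratio = k[idx] / kappa_forcing,
                 dk = 2 * pi / len, no_pattern = FALSE),
            class = "spectrum_result")
}

#' Linear growth rate of a spectral mode of the seagrass pattern
#'
#' Approximates the per-period growth rate of the mode nearest `kappa_n1`
#' from the spectral amplitudes at the start (post-noise) and end of a run:
#' \deqn{r_{n1} = \ln(A(t_{end}) / A(0)) / N_{periods}.}
#'
#' @param result [run_simulation()] output (uses `n1_initial`, `n1` and the
#'   number of periods run)
#' @param kappa_n1 wavenumber of the mode to track \[rad/m\]; default twice
#'   the forcing wavenumber (the Bragg-selected mode)
#' @return growth rate \[1 / forcing period\]
#' @export
growth_rate <- function(result, kappa_n1 = 2 * result$kappa) {
  sp0 <- pattern_spectrum(result$n1_initial, result$grid, result$kappa)
  sp1 <- pattern_spectrum(result$n1, result$grid, result$kappa)
  if (sp0$no_pattern)
    stop("zero initial amplitude: increase the initial noise")
  i <- which.min(abs(sp0$k - kappa_n1))
  a0 <- sp0$amplitude[i]; a1 <- sp1$amplitude[i]
  if (a0 == 0) stop("zero initial amplitude in the tracked bin")
  log(a1 / a0) / result$n_periods_run
}

#' Locate the modulation-instability threshold
#'
#' Scans the forcing amplitude for the sign change of the growth rate of the
#' Bragg mode (`kappa_n1 = 2 kappa`), then refines by bisection. Below the
#' returned amplitude `a_MI` the uniform vegetated meadow is stable to
#' modulations; above it, periodic perturbations at half the forcing
#' wavelength grow.
#'
#' @param a_grid increasing forcing amplitudes \[m\] spanning the sign change
#' @param config_fn function(a) returning the [sim_config()] to run at
#'   amplitude `a` (so callers control resolution and seeds)
#' @param tol bisection tolerance on `a` \[m\]
#' @return list: `a_MI`, `a_grid`, `rates` (growth rates on the grid),
#'   `n_runs`
#' @export
find_modulation_instability <- function(a_grid, config_fn, tol = NULL) {
  rate_at <- function(a) growth_rate(run_simulation(config_fn(a)))
  rates <- vapply(a_grid, rate_at, numeric(1))
  n_runs <- length(a_grid)
  pos <- which(rates > 0)
  if (length(pos) == 0 || pos[1] == 1)
    stop(sprintf(
      "no sign change of the growth rate on the grid (range %.3g to %.3g per period)",
      min(rates), max(rates)))
  lo <- a_grid[pos[1] - 1]; hi <- a_grid[pos[1]]
  if (is.null(tol)) tol <- 0.02 * hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    n_runs <- n_runs + 1
    if (r > 0) hi <- mid else lo <- mid
  }
  list(a_MI = (lo + hi) / 2, a_grid = a_grid, rates = rates, n_runs = n_runs)
}

#' Reflection coefficient of a frozen-topography run
#'
#' The envelope-maximum estimator: the maximum over interior nodes of the
#' final-period envelope of \eqn{|\eta_1| / a}. The run must have reached
#' dynamic equilibrium (interior envelope drift below the configured
#' tolerance per period over 5 consecutive periods) unless `require_equilibrium`
#' is disabled.
#'
#' @param result [run_simulation()] output of a `topography_frozen` run with
#'   `stop_on_equilibrium = TRUE`
#' @param require_equilibrium error if the run did not equilibrate
#' @return reflection coefficient `K_R` (dimensionless, >= 0)
#' @export
reflection_coefficient <- function(result, require_equilibrium = TRUE) {
  if (require_equilibrium && !result$equilibrated) {
    pm <- result$period_max_eta1
    drift <- if (length(pm) >= 2)
      max(abs(diff(utils::tail(pm, 6))) / pmax(utils::tail(pm, 5), 1e-300))
    else NA_real_
    stop(sprintf(
      "run not at dynamic equilibrium (final drift %.3g per period); extend n_periods",
      drift))
  }
  max(result$eta1_envelope[result$grid$interior]) / result$config$wp$a
}

#' Reflection-coefficient scan over forcing wavenumbers
#'
#' Freezes a seagrass pattern and measures the reflection coefficient for a
#' series of forcing wavenumbers bracketing the Bragg condition
#' \eqn{\kappa = \kappa_{n1}^*/2}, optionally for rescaled copies of the
#' pattern (the amplitude multipliers of the reference figure).
#'
#' @param pattern_result [run_simulation()] output of a pattern-forming run;
#'   supplies the frozen `n1` field, its dominant wavenumber and the basic
#'   state
#' @param kappa_ratios values of \eqn{2\kappa / \kappa_{n1}^*} to scan
#' @param amplitude_multipliers pattern amplitude rescalings (default 1)
#' @param n_periods_max cap on the run length while waiting for equilibrium
#' @param drift_tol dynamic-equilibrium drift tolerance per period
#' @return data frame of class `reflection_curve`: `kappa_ratio`,
#'   `multiplier`, `kappa` \[rad/m\], `K_R`, `equilibrated`; attribute
#'   `kappa_n1_star`
#' @export
reflection_scan <- function(pattern_result, kappa_ratios,
                            amplitude_multipliers = 1,
                            n_periods_max = 60, drift_tol = 0.01) {
  sp_pat <- pattern_spectrum(pattern_result$n1, pattern_result$grid,
                             pattern_result$kappa)
  if (sp_pat$no_pattern) stop("pattern run produced no pattern to freeze")
  kap_star <- sp_pat$k_dominant
  base <- pattern_result$config
  rows <- list()
  for (mult in amplitude_multipliers) {
    for (r in kappa_ratios) {
      kap_f <- r * kap_star / 2
      cfg <- sim_config(
        wp = base$wp, sp = base$sp,
        n_lambda_interior = base$n_lambda_interior,
        n_lambda_sponge = base$n_lambda_sponge,
        nodes_per_lambda = base$nodes_per_lambda,
        dt_frac = base$dt_frac,
        n_periods = n_periods_max,
        spinup_periods = base$spinup_periods,
        morph_accel = base$morph_accel, seed = base$seed,
        gamma_max = base$gamma_max, sponge_exponent = base$sponge_exponent,
        topography_frozen = TRUE,
        n1_init = mult * pattern_result$n1,
        basic_state = pattern_result$basic_state,
        kappa_forcing = kap_f, grid = pattern_result$grid,
        stop_on_equilibrium = TRUE, drift_tol = drift_tol)
      res <- run_simulation(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        kappa_ratio = r, multiplier = mult, kappa = kap_f,
        K_R = reflection_coefficient(res, require_equilibrium = FALSE),
        equilibrated = res$equilibrated)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "kappa_n1_star") <- kap_star
  class(out) <- c("reflection_curve", "data.frame")
  out
}

#' Mean crest-to-crest spacing of the interior pattern
#'
#' Finds interior local maxima of `n1` above a fraction of the largest value,
#' merges maxima closer than `min_sep`, and returns the mean spacing between
#' successive crests. Used to express the emerged pattern periodicity as a
#' fraction of the forcing wavelength.
#'
#' @param n1 field on the full grid
#' @param grid [sim_grid()]
#' @param min_height crest threshold as a fraction of the interior maximum
#' @param min_sep minimum crest separation \[m\] (closer maxima are merged,
#'   keeping the higher one)
#' @return mean crest spacing \[m\] (`NA` if fewer than 2 crests)
#' @export
crest_spacing <- function(n1, grid, min_height = 0.25, min_sep = 0) {
  xi <- grid$x[grid$interior]
  yi <- n1[grid$interior]
  m <- length(yi)
  is_max <- c(FALSE, yi[2:(m - 1)] > yi[1:(m - 2)] & yi[2:(m - 1)] >= yi[3:m], FALSE)
  is_max <- is_max & yi > min_height * max(yi)
  px <- xi[is_max]; py <- yi[is_max]
  if (min_sep > 0 && length(px) > 1) {
    keep_x <- px[1]; keep_y <- py[1]
    for (j in 2:length(px)) {
      if (px[j] - keep_x[length(keep_x)] < min_sep) {
        if (py[j] > keep_y[length(keep_y)]) {
          keep_x[length(keep_x)] <- px[j]; keep_y[length(keep_y)] <- py[j]
        }
      } else {
        keep_x <- c(keep_x, px[j]); keep_y <- c(keep_y, py[j])
      }
    }
    px <- keep_x
  }
  if (length(px) < 2) return(NA_real_)
  mean(diff(px))
}
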