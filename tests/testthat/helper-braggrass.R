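# small, fast configurations shared across test files

# a reduced-size coupled configuration for cheap smoke runs (not the study
# conditions; those live in default_pattern_config())
quick_config <- function(wp = wave_parameters(a = 0.3, T = 8),
                         sp = seagrass_params(), n_periods = 8, ...) {
  sim_config(wp = wp, sp = sp, n_lambda_interior = 6, n_lambda_sponge = 2,
             nodes_per_lambda = 32, n_periods = n_periods,
             spinup_periods = 3, ...)
}

# projection of a field onto cos/sin at wavenumber k over the interior
interior_projection <- function(field, grid, k) {
  xi <- grid$x[grid$interior]
  fi <- field[grid$interior]
  c(cos = 2 * mean(fi * cos(k * xi)), sin = 2 * mean(fi * sin(k * xi)))
}
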