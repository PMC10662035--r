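# keys accepted in a flat key: value configuration file, with the
# constructor that owns each one
.config_schema <- function() {
  list(
    wave = c("a", "T", "g", "rho", "f_w"),
    seagrass = c("omega_b", "omega_c", "alpha", "beta", "delta", "s", "h"),
    sim = c("n_lambda_interior", "n_lambda_sponge", "nodes_per_lambda",
            "dt_frac", "n_periods", "spinup_periods", "morph_accel", "seed",
            "init_noise_rel", "gamma_max", "sponge_exponent",
            "topography_frozen", "stop_on_equilibrium", "drift_tol",
            "store_snapshots")
  )
}

#' Load and validate a simulation configuration file
#'
#' Reads a flat `key: value` text file (one setting per line, `#` comments
#' allowed), merges it over the package defaults and validates every value
#' through the [wave_parameters()], [seagrass_params()] and [sim_config()]
#' constructors. Unknown keys are rejected with the full list of accepted
#' names.
#'
#' @param path configuration file
#' @return [sim_config()] object
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad))
    stop("unparseable config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  if (anyDuplicated(keys))
    stop("duplicate config key(s): ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  sch <- .config_schema()
  known <- unlist(sch, use.names = FALSE)
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; accepted keys: ", paste(known, collapse = ", "))
  parse_val <- function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) stop("non-numeric config value: ", v)
    num
  }
  vv <- lapply(vals, parse_val)
  names(vv) <- keys
  wp <- do.call(wave_parameters, vv[intersect(keys, sch$wave)])
  sp <- do.call(seagrass_params, vv[intersect(keys, sch$seagrass)])
  do.call(sim_config, c(list(wp = wp, sp = sp), vv[intersect(keys, sch$sim)]))
}

#' Write a configuration to a flat key: value file
#'
#' Inverse of [load_config()] for the scalar settings; round-trips through
#' [load_config()] to an equivalent configuration.
#'
#' @param config [sim_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  sch <- .config_schema()
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 17)
  }
  lines <- c(
    vapply(sch$wave, function(k) sprintf("%s: %s", k, fmt(config$wp[[k]])), character(1)),
    vapply(sch$seagrass, function(k) sprintf("%s: %s", k, fmt(config$sp[[k]])), character(1)),
    vapply(sch$sim, function(k) sprintf("%s: %s", k, fmt(config[[k]])), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a wave-climate CSV file
#'
#' Comma-separated text with header columns `time` (ISO-8601, UTC), `hs_m`,
#' `tp_s` in any column order. Invalid rows are reported by row number.
#'
#' @param path input file
#' @param site_depth depth at the climate point \[m\]
#' @param site_label free-text label
#' @return [wave_climate()] object
#' @export
read_climate_csv <- function(path, site_depth, site_label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "hs_m", "tp_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  tm <- rep(as.POSIXct(NA), nrow(df))
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    miss <- is.na(tm)
    if (!any(miss)) break
    tm[miss] <- as.POSIXct(strptime(df$time[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(tm))
  if (length(bad))
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  wave_climate(tm, as.numeric(df$hs_m), as.numeric(df$tp_s),
               site_depth = site_depth, site_label = site_label)
}

#' Write a wave-climate series to CSV
#'
#' Fixed column order `time,hs_m,tp_s` (ISO-8601 UTC timestamps) plus any
#' derived columns present; read back with [read_climate_csv()].
#'
#' @param series [wave_climate()] object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_climate_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$time <- format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  first <- c("time", "hs_m", "tp_s")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a seagrass pattern-observation CSV file
#'
#' Header columns `depth_m`, `pattern_wavelength_m` and optionally `site`,
#' in any order; both numeric columns must be positive.
#'
#' @param path input file
#' @return data frame `depth_m`, `pattern_wavelength_m`, `site`
#' @export
read_observations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("depth_m", "pattern_wavelength_m")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$depth_m) | df$depth_m <= 0 |
               !is.finite(df$pattern_wavelength_m) | df$pattern_wavelength_m <= 0)
  if (length(bad))
    stop("invalid observation row(s): ", paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(df$site)) df$site <- ""
  df[, c("depth_m", "pattern_wavelength_m", "site")]
}

#' Write a run manifest
#'
#' JSON record sufficient to re-run a deterministic stage bit-identically:
#' the full flattened parameter set, the seed, package version, digests of
#' any input files, and timestamps.
#'
#' @param config [sim_config()] (or any named list of parameters)
#' @param path output JSON file
#' @param inputs character vector of input file paths to digest (md5)
#' @param extra named list of additional fields to record
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(config, path, inputs = character(0), extra = list()) {
  flat <- if (inherits(config, "sim_config")) {
    c(config$wp[c("a", "T", "g", "rho", "f_w")],
      unclass(config$sp),
      config[setdiff(.config_schema()$sim, character(0))])
  } else config
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(
    tool = "braggrass",
    version = as.character(utils::packageVersion("braggrass")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = flat$seed,
    input_digests = digests,
    parameters = flat
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
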