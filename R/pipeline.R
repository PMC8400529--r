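# Configuration and end-to-end orchestration.
#
# A run configuration selects the scenario grid (water classes, zenith and
# cloud ranges), the spectral mode (5 nm, or 10 nm for coarse fast runs),
# the noise level, the analysis depth ranges, and output handling. The
# pipeline is deterministic for a fixed configuration: per-scenario seeds
# derive from `base_seed`, and the default noise-free mode uses no
# randomness at all.

.legal_depth_ranges <- c(0.2, 0.5, 1, 1.5, 5, 10)

#' Default run configuration
#'
#' The full simulation grid: all 7 water classes, solar zenith 0-80 deg,
#' cloud cover 0-100%, 5 nm spectra, noise-free, seed 12345, analysis
#' depth ranges 0.2-10 m and ratio depths 0.2-10 m.
#'
#' @return a named list of class `annulight_config`.
#' @export
default_config <- function() {
  structure(
    list(
      base_seed = 12345L,
      classes = water_classes()$water_class,
      zenith = seq(0, 80, by = 10),
      cloud = seq(0, 1, by = 0.2),
      spectral_res = 5,
      noise_sd = 0,
      depth_ranges = .legal_depth_ranges,
      ratio_depths = .legal_depth_ranges,
      out_dir = NULL,
      verbosity = 1
    ),
    class = "annulight_config"
  )
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration file, fills unset keys with the defaults of
#' [default_config()], and validates every value against the legal grids.
#' An empty file yields the full default configuration. Unknown keys and
#' illegal values raise an error naming the key.
#'
#' @param path path to a YAML file.
#' @return an `annulight_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_config(raw)
}

#' @rdname load_config
#' @param x a named list of configuration values (partial is fine).
#' @export
as_config <- function(x) {
  defaults <- default_config()
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(unclass(defaults), x, keep.null = TRUE)

  if (!all(cfg$classes %in% water_classes()$water_class)) {
    abort("Config key 'classes': unknown water class name.")
  }
  if (!all(cfg$zenith %in% seq(0, 80, by = 10))) {
    abort("Config key 'zenith': values must lie on seq(0, 80, by = 10).")
  }
  if (!all(vapply(cfg$cloud,
                  function(x) any(abs(x - seq(0, 1, 0.2)) < 1e-9), logical(1)))) {
    abort("Config key 'cloud': values must lie on seq(0, 1, by = 0.2).")
  }
  if (!cfg$spectral_res %in% c(5, 10)) {
    abort("Config key 'spectral_res': must be 5 or 10 (nm).")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    abort("Config key 'noise_sd': must be a non-negative number.")
  }
  if (!all(vapply(cfg$depth_ranges,
                  function(x) any(abs(x - .legal_depth_ranges) < 1e-9),
                  logical(1)))) {
    abort("Config key 'depth_ranges': must be a subset of 0.2, 0.5, 1, 1.5, 5, 10.")
  }
  if (!is.null(cfg$ratio_depths) &&
      !all(vapply(cfg$ratio_depths,
                  function(x) any(abs(x - .legal_depth_ranges) < 1e-9),
                  logical(1)))) {
    abort("Config key 'ratio_depths': must be a subset of 0.2, 0.5, 1, 1.5, 5, 10.")
  }
  cfg$base_seed <- as.integer(cfg$base_seed)
  if (is.na(cfg$base_seed)) abort("Config key 'base_seed': must be an integer.")
  structure(cfg, class = "annulight_config")
}

#' Save a configuration to YAML
#'
#' @param config an `annulight_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "annulight_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.annulight_config <- function(x, ...) {
  cat("<annulight_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

.log <- function(cfg, level, ...) {
  if (cfg$verbosity >= level) message(sprintf(...))
}

# CSV with a provenance comment header (config hash + seed)
.write_csv_prov <- function(df, path, stamp) {
  readr::write_lines(stamp, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full annular-irradiance assessment pipeline
#'
#' End to end: enumerate the scenario grid, generate every synthetic
#' radiance field, integrate irradiance profiles, fit the regression
#' attenuation coefficients, and compute the assessment products (ratio
#' statistics, per-lighting-cell correlation/slope heat-map tables for
#' Ea40 and Ea50, average-slope and relative-error tables). If
#' `config$out_dir` is set, all tables are persisted as CSV with a
#' provenance header (configuration hash and base seed).
#'
#' @param config an `annulight_config`, e.g. [default_config()] or
#'   [load_config()]. Unset keys are filled with defaults.
#' @return an object of class `annulight_run`: list with `config`,
#'   `scenarios`, `k_table`, `ratio_stats`, `heatmaps` (per band),
#'   `assessment` (a [slope_and_error_tables()] object) and `timing`
#'   (seconds).
#' @export
run_pipeline <- function(config = default_config()) {
  if (!inherits(config, "annulight_config")) config <- as_config(config)
  t0 <- Sys.time()

  grid <- build_grid()
  classes <- filter(water_classes(), .data$water_class %in% config$classes)
  scenarios <- scenario_grid(
    zenith = config$zenith, cloud = config$cloud, classes = classes,
    base_seed = config$base_seed, noise_sd = config$noise_sd
  )
  .log(config, 1, "annulight: %d scenarios (%d classes x 8 corners x %d zenith x %d cloud)",
       nrow(scenarios), nrow(classes), length(config$zenith), length(config$cloud))

  wavelengths <- seq(400, 700, by = config$spectral_res)
  tables <- grid_tables(
    scenarios, grid,
    wavelengths = wavelengths,
    depth_ranges = config$depth_ranges,
    ratio_depths = config$ratio_depths,
    verbose = config$verbosity >= 2
  )
  .log(config, 1, "annulight: attenuation fitted for %d scenario-band-range rows",
       nrow(tables$k_table))

  ratio_stats <- if (!is.null(tables$ratio_table)) {
    ratio_analysis(tables$ratio_table)
  }

  hm_range <- max(config$depth_ranges[config$depth_ranges <= 1.5 + 1e-9],
                  min(config$depth_ranges))
  heatmaps <- lapply(
    setNames(nm = c("Ea40", "Ea50")),
    function(b) lighting_heatmaps(tables$k_table, band = b,
                                  depth_range = hm_range)
  )
  assessment <- slope_and_error_tables(
    tables$k_table, bands = c("Ea40", "Ea50"),
    depth_ranges = config$depth_ranges
  )
  timing <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  .log(config, 1, "annulight: pipeline finished in %.1f s", timing)

  run <- structure(
    list(
      config = config, scenarios = scenarios,
      k_table = tables$k_table, ratio_table = tables$ratio_table,
      ratio_stats = ratio_stats, heatmaps = heatmaps,
      assessment = assessment, timing = timing
    ),
    class = "annulight_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Persist the tables of a pipeline run
#'
#' Writes scenarios, the attenuation table, ratio statistics, heat-map
#' tables and the slope/error tables as CSV files under `dir`, each with a
#' provenance comment line (configuration hash and base seed).
#'
#' @param run an `annulight_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "annulight_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # hash only the keys that determine the numbers (not output handling)
  sci <- unclass(run$config)
  sci <- sci[setdiff(names(sci), c("out_dir", "verbosity"))]
  stamp <- sprintf("# annulight run | config_hash=%s | base_seed=%d",
                   rlang::hash(sci), run$config$base_seed)
  .write_csv_prov(run$scenarios, file.path(dir, "scenarios.csv"), stamp)
  .write_csv_prov(run$k_table, file.path(dir, "k_table.csv"), stamp)
  if (!is.null(run$ratio_stats)) {
    .write_csv_prov(run$ratio_stats, file.path(dir, "ratio_stats.csv"), stamp)
  }
  for (b in names(run$heatmaps)) {
    .write_csv_prov(run$heatmaps[[b]],
                    file.path(dir, sprintf("heatmap_%s.csv", b)), stamp)
  }
  a <- run$assessment
  .write_csv_prov(a$slope_table, file.path(dir, "slope_table.csv"), stamp)
  .write_csv_prov(a$error_table, file.path(dir, "error_table.csv"), stamp)
  .write_csv_prov(a$cell_errors, file.path(dir, "cell_errors.csv"), stamp)
  .write_csv_prov(a$water_type_errors,
                  file.path(dir, "water_type_errors.csv"), stamp)
  invisible(dir)
}

#' Re-assess a persisted attenuation table
#'
#' Runs the assessment stage alone on a previously computed K table (as
#' written by [write_run()]), so that partial reruns reproduce full-run
#' results without regenerating radiance fields.
#'
#' @param path path to a `k_table.csv` written by [write_run()].
#' @param bands annular bands to assess.
#' @param depth_ranges depth ranges to assess (default: all in the table).
#' @return a `kd_assessment` object.
#' @export
assess_k_table <- function(path, bands = c("Ea40", "Ea50"),
                           depth_ranges = NULL) {
  k_table <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                             progress = FALSE)
  if (is.null(depth_ranges)) depth_ranges <- sort(unique(k_table$z_max))
  slope_and_error_tables(k_table, bands = bands, depth_ranges = depth_ranges)
}

#' @export
print.annulight_run <- function(x, ...) {
  cat("<annulight_run>\n")
  cat(sprintf("  %d scenarios | spectral res %g nm | noise sd %g | %.1f s\n",
              nrow(x$scenarios), x$config$spectral_res, x$config$noise_sd,
              x$timing))
  print(x$assessment)
  invisible(x)
}
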