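# Diffuse attenuation coefficients from irradiance profiles.
#
# Two estimators: the two-depth formula
# K = ln(E(z1)/E(z2)) / (z2 - z1), and ordinary least-squares regression of
# ln E on depth (K = minus the slope), which is the estimator used for all
# profile-based analyses. Depth 0 is never part of a profile (the grid
# starts at 0.02 m); a depth range "0-1.5 m" means all grid depths <= 1.5.

#' Two-depth diffuse attenuation coefficient
#'
#' \eqn{\bar K = \ln(E_1/E_2)/(z_2 - z_1)} between two measurement depths.
#'
#' @param E1,E2 irradiances at depths `z1` and `z2`; must be positive.
#' @param z1,z2 depths in metres with `z2 > z1`.
#' @return attenuation coefficient in m-1.
#' @examples
#' k_two_depth(10, 5, 0.5, 1.5) # ln 2
#' @export
k_two_depth <- function(E1, E2, z1, z2) {
  if (any(E1 <= 0) || any(E2 <= 0)) {
    abort("Irradiances must be positive for the two-depth formula.")
  }
  if (any(z2 <= z1)) abort("`z2` must be greater than `z1`.")
  log(E1 / E2) / (z2 - z1)
}

#' Regression-based diffuse attenuation coefficient
#'
#' Ordinary least-squares fit of `ln E` against depth; K is the negative
#' of the slope. At least three depths with positive irradiance are
#' required. A constant profile gives `K = 0` with `r_squared` flagged as
#' `NA` (the fit is degenerate).
#'
#' @param depths depths in metres.
#' @param E irradiances at `depths`; all positive.
#' @return a one-row tibble: `K` (m-1), `r_squared`, `n_depths`,
#'   `z_min`, `z_max`, `method = "regression"`.
#' @examples
#' z <- depth_grid(1.5)
#' k_regression(z, exp(-0.7 * z))
#' @export
k_regression <- function(depths, E) {
  if (length(depths) != length(E)) {
    abort("`depths` and `E` must have equal length.")
  }
  if (length(depths) < 3) {
    abort("At least 3 depths are required for a regression K.")
  }
  if (any(E <= 0)) abort("All irradiances must be positive.")
  fit <- .k_ols(depths, matrix(log(E), ncol = 1))
  tibble::tibble(
    K = fit$K, r_squared = fit$r_squared,
    n_depths = length(depths), z_min = min(depths), z_max = max(depths),
    method = "regression"
  )
}

# vectorised OLS of each column of ln_E on z; returns K = -slope and R^2
.k_ols <- function(z, ln_E) {
  zc <- z - mean(z)
  szz <- sum(zc^2)
  yc <- sweep(ln_E, 2, colMeans(ln_E))
  szy <- drop(crossprod(zc, yc))
  syy <- colSums(yc^2)
  slope <- szy / szz
  r2 <- ifelse(syy > 0, szy^2 / (szz * syy), NA_real_)
  list(K = -slope, r_squared = r2)
}

#' Attenuation coefficients of a profile over standard depth ranges
#'
#' Regression-based K for the PAR planar irradiance (`Ed`) and each of the
#' eight annular PAR irradiances (`Ea10`..`Ea80`), over each requested
#' depth range. A range `r` uses every profile depth `<= r` (the grid
#' starts at 0.02 m, so depth 0 never enters a fit).
#'
#' @param profile an [irradiance_profile()].
#' @param depth_ranges upper ends of the depth ranges in metres; default
#'   the standard set 0.2, 0.5, 1, 1.5, 5, 10.
#' @return a tibble with one row per band and range: `band`, `z_max`, `K`,
#'   `r_squared`, `n_depths`.
#' @examples
#' grid <- build_grid()
#' sc <- scenario_grid(zenith = 30, cloud = 0.2)[1, ]
#' fld <- generate_field(sc, grid, wavelengths = seq(400, 700, 20),
#'                       depths = depth_grid(1.5))
#' k_profiles(irradiance_profile(fld, grid), depth_ranges = 1.5)
#' @export
k_profiles <- function(profile, depth_ranges = c(0.2, 0.5, 1, 1.5, 5, 10)) {
  stopifnot(inherits(profile, "irradiance_profile"))
  if (length(depth_ranges) == 0) abort("`depth_ranges` must be non-empty.")
  bands <- c("Ed", paste0("Ea", profile$theta_bands))
  E <- cbind(profile$Ed_par, profile$Ea_par)
  out <- vector("list", length(depth_ranges))
  for (i in seq_along(depth_ranges)) {
    r <- depth_ranges[[i]]
    idx <- which(profile$depths <= r + 1e-9)
    if (length(idx) < 3) {
      abort(sprintf("Depth range 0-%g m contains fewer than 3 grid depths.", r))
    }
    Es <- E[idx, , drop = FALSE]
    if (any(Es <= 0)) {
      abort(sprintf("Non-positive irradiance inside depth range 0-%g m.", r))
    }
    fit <- .k_ols(profile$depths[idx], log(Es))
    out[[i]] <- tibble::tibble(
      band = bands, z_max = r, K = fit$K, r_squared = fit$r_squared,
      n_depths = length(idx)
    )
  }
  bind_rows(out)
}

#' Attenuation and ratio tables over a scenario set
#'
#' Runs the generator and the irradiance/attenuation stack over every
#' scenario of a [scenario_grid()] tibble in one pass: per scenario it
#' generates the radiance field, integrates the PAR irradiance profile,
#' fits regression K for `Ed` and `Ea10`..`Ea80` over each depth range,
#' and (optionally) records the annular-to-planar log ratios at the
#' analysis depths.
#'
#' @param scenarios a [scenario_grid()] tibble (any subset of rows).
#' @param grid a [build_grid()] object.
#' @param wavelengths wavelength grid, nm: `seq(400, 700, 5)` (default) or
#'   the coarse `seq(400, 700, 10)` mode.
#' @param depths depth grid, m; defaults to the Table-style grid truncated
#'   at the largest depth needed.
#' @param depth_ranges depth-range upper ends for the K fits.
#' @param ratio_depths depths (m) at which to record `log10(Ea/Ed)` per
#'   band, or `NULL` to skip; must be members of `depths`.
#' @param verbose print progress every 500 scenarios.
#' @return a list with `k_table` (scenario metadata + `band`, `z_max`, `K`,
#'   `r_squared`) and `ratio_table` (`NULL` unless `ratio_depths` given:
#'   scenario metadata + `depth`, `theta_band`, `log_ratio`).
#' @export
grid_tables <- function(scenarios, grid,
                        wavelengths = seq(400, 700, by = 5),
                        depths = NULL,
                        depth_ranges = c(0.2, 0.5, 1, 1.5, 5, 10),
                        ratio_depths = NULL,
                        verbose = FALSE) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) > 0)
  if (is.null(depths)) {
    depths <- depth_grid(max_depth = max(depth_ranges, ratio_depths))
  }
  if (!is.null(ratio_depths)) {
    miss <- ratio_depths[!vapply(
      ratio_depths, function(z) any(abs(depths - z) < 1e-9), logical(1)
    )]
    if (length(miss)) {
      abort(paste0("`ratio_depths` not on the depth grid: ",
                   paste(miss, collapse = ", ")))
    }
  }

  n <- nrow(scenarios)
  k_out <- vector("list", n)
  r_out <- if (!is.null(ratio_depths)) vector("list", n)
  meta_cols <- c("scenario_id", "water_class", "corner", "solar_zenith",
                 "cloud_fraction")
  for (i in seq_len(n)) {
    sc <- scenarios[i, ]
    stage <- "generate_field"
    res <- tryCatch({
      fld <- generate_field(sc, grid, wavelengths = wavelengths, depths = depths)
      stage <- "irradiance_profile"
      irradiance_profile(fld, grid)
    }, error = function(e) {
      abort(sprintf("Stage '%s' failed for scenario '%s': %s",
                    stage, sc$scenario_id, conditionMessage(e)))
    })
    prof <- res
    k_out[[i]] <- dplyr::bind_cols(
      sc[rep(1, length(depth_ranges) * (1 + length(prof$theta_bands))), meta_cols],
      k_profiles(prof, depth_ranges)
    )
    if (!is.null(ratio_depths)) {
      iz <- vapply(ratio_depths, function(z) which(abs(depths - z) < 1e-9)[1],
                   integer(1))
      lr <- log10(prof$Ea_par[iz, , drop = FALSE] / prof$Ed_par[iz])
      r_out[[i]] <- dplyr::bind_cols(
        sc[rep(1, length(iz) * length(prof$theta_bands)), meta_cols],
        tibble::tibble(
          depth = rep(ratio_depths, times = length(prof$theta_bands)),
          theta_band = rep(prof$theta_bands, each = length(iz)),
          log_ratio = as.vector(lr)
        )
      )
    }
    if (verbose && i %% 500 == 0) {
      message(sprintf("  ... %d / %d scenarios", i, n))
    }
  }
  list(
    k_table = bind_rows(k_out),
    ratio_table = if (!is.null(ratio_depths)) bind_rows(r_out)
  )
}

#' @rdname grid_tables
#' @return `grid_k_table()` returns just the attenuation tibble.
#' @export
grid_k_table <- function(scenarios, grid,
                         wavelengths = seq(400, 700, by = 5),
                         depths = NULL,
                         depth_ranges = c(0.2, 0.5, 1, 1.5, 5, 10),
                         verbose = FALSE) {
  grid_tables(scenarios, grid, wavelengths, depths, depth_ranges,
              ratio_depths = NULL, verbose = verbose)$k_table
}

#' @rdname grid_tables
#' @return `grid_ratio_table()` returns just the log-ratio tibble.
#' @export
grid_ratio_table <- function(scenarios, grid,
                             wavelengths = seq(400, 700, by = 5),
                             depths = NULL,
                             ratio_depths = c(0.2, 0.5, 1, 1.5, 5, 10),
                             verbose = FALSE) {
  if (is.null(depths)) depths <- depth_grid(max_depth = max(ratio_depths))
  grid_tables(scenarios, grid, wavelengths, depths,
              depth_ranges = max(ratio_depths), ratio_depths = ratio_depths,
              verbose = verbose)$ratio_table
}
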