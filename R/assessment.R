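# Assessment analyses: optimal annular angle, Ka-Kd correlation and slope,
# lighting-scenario heat-maps, slope tables and relative-error maps.
#
# The central question: how well does the annular attenuation Ka(theta_i)
# stand in for the planar Kd? The per-lighting-cell regression slope m
# converts Ka to an estimate Kd_hat = Ka / m_bar (m_bar the average slope
# over cells at a fixed depth range), and the relative error
# eps = (Kd_hat - Kd)/Kd * 100 maps where the proxy degrades.

#' Mean and spread of the annular/planar log ratio per band and depth
#'
#' Aggregates a `ratio_table` from [grid_ratio_table()] into the statistics
#' used to choose the optimal annular angle: mean and standard deviation of
#' `log10(Ea(theta_i)/Ed)` across scenarios, per band and analysis depth.
#'
#' @param ratio_table tibble with columns `theta_band`, `depth`,
#'   `log_ratio` (one row per scenario, band and depth).
#' @param depths optional subset of analysis depths to keep.
#' @return tibble: `theta_band`, `depth`, `n`, `mean_log_ratio`,
#'   `sd_log_ratio`.
#' @export
ratio_analysis <- function(ratio_table, depths = NULL) {
  stopifnot(all(c("theta_band", "depth", "log_ratio") %in% names(ratio_table)))
  if (nrow(ratio_table) == 0) abort("`ratio_table` is empty.")
  if (!is.null(depths)) {
    ratio_table <- filter(ratio_table, .data$depth %in% depths)
    if (nrow(ratio_table) == 0) abort("No rows at the requested depths.")
  }
  ratio_table %>%
    group_by(.data$theta_band, .data$depth) %>%
    summarise(
      n = dplyr::n(),
      mean_log_ratio = mean(.data$log_ratio),
      sd_log_ratio = if (dplyr::n() > 1) stats::sd(.data$log_ratio) else 0,
      .groups = "drop"
    )
}

#' Correlation and regression slope between two attenuation sets
#'
#' Pearson correlation coefficient r and the least-squares slope m of the
#' regression of `ka` (response) on `kd` (predictor), the orientation for
#' which `Kd_hat = Ka / m` recovers `Kd` when the relation is exact. The
#' significance of r (two-sided test) is reported alongside.
#'
#' @param kd,ka equal-length numeric vectors, `n >= 3`.
#' @return one-row tibble: `n`, `r`, `m`, `intercept`, `p_value`. A
#'   constant `ka` gives `m = 0` and `r = NA` (flagged degenerate).
#' @examples
#' scatter_stats(1:10, 1.1 * (1:10))
#' @export
scatter_stats <- function(kd, ka) {
  if (length(kd) != length(ka)) abort("`kd` and `ka` must have equal length.")
  if (length(kd) < 3) abort("At least 3 pairs are required.")
  if (var(kd) == 0) abort("`kd` has zero variance; the regression is undefined.")
  m <- stats::cov(kd, ka) / var(kd)
  if (var(ka) == 0) {
    return(tibble::tibble(
      n = length(kd), r = NA_real_, m = 0, intercept = mean(ka),
      p_value = NA_real_
    ))
  }
  ct <- suppressWarnings(cor.test(kd, ka))
  tibble::tibble(
    n = length(kd),
    r = unname(ct$estimate),
    m = m,
    intercept = mean(ka) - m * mean(kd),
    p_value = ct$p.value
  )
}

# wide (Kd, Ka_band) pairs at one depth range from a tidy k table
.kd_ka_pairs <- function(k_table, band, depth_range, kd_band = "Ed") {
  need <- c("scenario_id", "solar_zenith", "cloud_fraction", "band", "z_max", "K")
  stopifnot(all(need %in% names(k_table)))
  band_sel <- c(kd_band, band)
  sub <- filter(k_table, abs(.data$z_max - depth_range) < 1e-9,
                .data$band %in% band_sel)
  if (nrow(sub) == 0) {
    abort(sprintf("No K rows at depth range 0-%g m.", depth_range))
  }
  keep <- intersect(
    c("scenario_id", "water_class", "corner", "solar_zenith", "cloud_fraction"),
    names(sub)
  )
  wide <- sub %>%
    select(all_of(keep), "band", "K") %>%
    tidyr::pivot_wider(names_from = "band", values_from = "K") %>%
    rename(kd = all_of(kd_band), ka = all_of(band))
  if (any(is.na(wide$kd)) || any(is.na(wide$ka))) {
    abort(sprintf("Missing K values for bands %s/%s.", kd_band, band))
  }
  wide
}

#' Per-lighting-cell correlation and slope heat-map table
#'
#' Splits the scenario set by (solar zenith, cloud cover) cell and computes
#' [scatter_stats()] between Kd and the chosen annular band's Ka within
#' each cell (the points of a cell are the water classes and concentration
#' corners, 56 on the full grid). The lattice must be complete: every
#' observed zenith level crossed with every observed cloud level.
#'
#' @param k_table tidy attenuation table from [grid_k_table()].
#' @param band annular band name, e.g. `"Ea40"`.
#' @param depth_range depth-range upper end in metres (default 1.5).
#' @return tibble: `solar_zenith`, `cloud_fraction`, `n`, `r`, `m`,
#'   `intercept`, `p_value`.
#' @export
lighting_heatmaps <- function(k_table, band = "Ea40", depth_range = 1.5) {
  wide <- .kd_ka_pairs(k_table, band, depth_range)
  zen <- sort(unique(wide$solar_zenith))
  cld <- sort(unique(wide$cloud_fraction))
  cells <- wide %>%
    group_by(.data$solar_zenith, .data$cloud_fraction) %>%
    summarise(stats = list(scatter_stats(.data$kd, .data$ka)),
              .groups = "drop") %>%
    tidyr::unnest("stats")
  if (nrow(cells) != length(zen) * length(cld)) {
    abort("Empty lighting cell: the (zenith x cloud) lattice is incomplete.")
  }
  cells
}

#' Average slopes, Kd reconstruction and relative-error tables
#'
#' For each annular band and depth range: computes the per-lighting-cell
#' regression slopes of Ka on Kd, averages them into \eqn{\bar m},
#' reconstructs every scenario's planar attenuation as
#' \eqn{\hat K_d = K_a / \bar m}, and summarises the relative error
#' \eqn{\epsilon_K = (\hat K_d - K_d)/K_d \times 100} (in percent) overall,
#' per lighting cell, and per water type.
#'
#' @param k_table tidy attenuation table from [grid_k_table()]; must
#'   contain every requested depth range.
#' @param bands annular band names (default the optimal band `"Ea40"` and
#'   its neighbour `"Ea50"`).
#' @param depth_ranges depth-range upper ends, m.
#' @return an object of class `kd_assessment`: list of tibbles
#'   \describe{
#'     \item{slope_table}{`band`, `z_max`, `m_bar` (mean of cell slopes).}
#'     \item{error_table}{`band`, `z_max`, `mean_abs_rel_error` (fraction,
#'       i.e. mean |eps|/100).}
#'     \item{cell_errors}{per (band, z_max, zenith, cloud): `n`,
#'       `mean_abs_err_pct`, `mean_err_pct`.}
#'     \item{water_type_errors}{the same statistics further split by
#'       `water_class`.}
#'     \item{errors}{per-scenario `eps_pct` values.}
#'   }
#' @export
slope_and_error_tables <- function(k_table, bands = c("Ea40", "Ea50"),
                                   depth_ranges = c(0.2, 0.5, 1, 1.5, 5, 10)) {
  have <- unique(k_table$z_max)
  miss <- depth_ranges[!vapply(
    depth_ranges, function(r) any(abs(have - r) < 1e-9), logical(1)
  )]
  if (length(miss)) {
    abort(paste0("Depth ranges missing from `k_table`: ",
                 paste(miss, collapse = ", ")))
  }

  combos <- tidyr::expand_grid(band = bands, z_max = depth_ranges)
  pieces <- purrr::pmap(combos, function(band, z_max) {
    wide <- .kd_ka_pairs(k_table, band, z_max)
    cell_m <- wide %>%
      group_by(.data$solar_zenith, .data$cloud_fraction) %>%
      summarise(m = stats::cov(.data$kd, .data$ka) / var(.data$kd),
                .groups = "drop")
    m_bar <- mean(cell_m$m)
    err <- wide %>%
      mutate(
        band = band, z_max = z_max,
        kd_hat = .data$ka / m_bar,
        eps_pct = (.data$kd_hat - .data$kd) / .data$kd * 100
      )
    list(
      slope = tibble::tibble(band = band, z_max = z_max, m_bar = m_bar),
      errors = err
    )
  })

  errors <- bind_rows(purrr::map(pieces, "errors"))
  slope_table <- bind_rows(purrr::map(pieces, "slope"))
  error_table <- errors %>%
    group_by(.data$band, .data$z_max) %>%
    summarise(mean_abs_rel_error = mean(abs(.data$eps_pct)) / 100,
              .groups = "drop")
  cell_errors <- errors %>%
    group_by(.data$band, .data$z_max, .data$solar_zenith, .data$cloud_fraction) %>%
    summarise(
      n = dplyr::n(),
      mean_abs_err_pct = mean(abs(.data$eps_pct)),
      mean_err_pct = mean(.data$eps_pct),
      .groups = "drop"
    )
  water_type_errors <- errors %>%
    group_by(.data$band, .data$z_max, .data$water_class,
             .data$solar_zenith, .data$cloud_fraction) %>%
    summarise(
      n = dplyr::n(),
      mean_abs_err_pct = mean(abs(.data$eps_pct)),
      mean_err_pct = mean(.data$eps_pct),
      .groups = "drop"
    )

  structure(
    list(
      slope_table = slope_table,
      error_table = error_table,
      cell_errors = cell_errors,
      water_type_errors = water_type_errors,
      errors = errors
    ),
    class = "kd_assessment"
  )
}

#' @export
print.kd_assessment <- function(x, ...) {
  cat("<kd_assessment>\n")
  cat("Average slopes (m_bar) per band and depth range:\n")
  print(tidyr::pivot_wider(x$slope_table, names_from = "z_max",
                           values_from = "m_bar"))
  cat("Mean absolute relative error (fraction):\n")
  print(tidyr::pivot_wider(x$error_table, names_from = "z_max",
                           values_from = "mean_abs_rel_error"))
  invisible(x)
}

#' Tidy a Kd assessment
#'
#' @param x a `kd_assessment`.
#' @param ... unused.
#' @return long tibble of `band`, `z_max`, `metric`, `value` combining the
#'   average-slope and mean-error tables.
#' @method tidy kd_assessment
#' @export
tidy.kd_assessment <- function(x, ...) {
  bind_rows(
    x$slope_table %>%
      rename(value = "m_bar") %>% mutate(metric = "mean_slope"),
    x$error_table %>%
      rename(value = "mean_abs_rel_error") %>%
      mutate(metric = "mean_abs_rel_error")
  ) %>%
    select("band", "z_max", "metric", "value")
}

#' One-row summary of a Kd assessment
#'
#' @param x a `kd_assessment`.
#' @param ... unused.
#' @return one-row tibble: scenario count, the worst per-cell mean
#'   absolute error (percent) per band at the deepest common range, and
#'   the overall mean absolute relative error.
#' @method glance kd_assessment
#' @export
glance.kd_assessment <- function(x, ...) {
  z0 <- max(x$error_table$z_max)
  worst <- x$cell_errors %>%
    filter(abs(.data$z_max - z0) < 1e-9) %>%
    group_by(.data$band) %>%
    summarise(max_cell = max(.data$mean_abs_err_pct), .groups = "drop")
  out <- tibble::tibble(
    n_scenarios = length(unique(x$errors$scenario_id)),
    z_max = z0,
    mean_abs_rel_error = mean(x$error_table$mean_abs_rel_error)
  )
  for (i in seq_len(nrow(worst))) {
    out[[paste0("max_cell_err_", worst$band[i])]] <- worst$max_cell[i]
  }
  out
}
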