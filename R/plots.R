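# Plot helpers. All return ggplot objects so callers can restyle them.

#' Bar plot of the annular/planar log-ratio statistics
#'
#' Mean `log10(Ea/Ed)` per annular band with one-standard-deviation error
#' bars, at one analysis depth: the figure used to pick the optimal
#' annular angle.
#'
#' @param ratio_stats output of [ratio_analysis()].
#' @param depth which analysis depth to show (default 1.5 m).
#' @return a ggplot.
#' @export
plot_ratio_bars <- function(ratio_stats, depth = 1.5) {
  df <- filter(ratio_stats, abs(.data$depth - !!depth) < 1e-9)
  if (nrow(df) == 0) abort("No ratio statistics at the requested depth.")
  ggplot(df, aes(x = factor(.data$theta_band), y = .data$mean_log_ratio)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(
      aes(ymin = .data$mean_log_ratio - .data$sd_log_ratio,
          ymax = .data$mean_log_ratio + .data$sd_log_ratio),
      width = 0.25
    ) +
    labs(
      x = "annular band centre (degrees)",
      y = expression(log[10] * "(Ea/Ed)"),
      title = sprintf("Annular/planar irradiance ratio at %.1f m", depth)
    ) +
    theme_minimal()
}

#' Heat-map of a per-lighting-cell metric
#'
#' @param cells tibble with `solar_zenith`, `cloud_fraction` and the
#'   metric column (e.g. from [lighting_heatmaps()] or the `cell_errors`
#'   table of [slope_and_error_tables()]).
#' @param metric name of the column to fill by (default `"r"`).
#' @return a ggplot tile map (zenith on x, cloud cover on y).
#' @export
plot_lighting_heatmap <- function(cells, metric = "r") {
  if (!metric %in% names(cells)) {
    abort(sprintf("Column '%s' not found in `cells`.", metric))
  }
  ggplot(cells, aes(
    x = factor(.data$solar_zenith),
    y = factor(100 * .data$cloud_fraction),
    fill = .data[[metric]]
  )) +
    geom_tile() +
    scale_fill_viridis_c(name = metric) +
    labs(x = "solar zenith angle (degrees)", y = "cloud cover (%)") +
    theme_minimal()
}

#' Scatter plot of Kd against an annular Ka
#'
#' @param k_table tidy attenuation table from [grid_k_table()].
#' @param band annular band name (default `"Ea40"`).
#' @param depth_range depth-range upper end, m.
#' @return a ggplot with the pooled least-squares line.
#' @export
plot_kd_ka_scatter <- function(k_table, band = "Ea40", depth_range = 1.5) {
  wide <- .kd_ka_pairs(k_table, band, depth_range)
  st <- scatter_stats(wide$kd, wide$ka)
  ggplot(wide, aes(x = .data$kd, y = .data$ka, colour = .data$water_class)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_abline(slope = st$m, intercept = st$intercept, linetype = 2) +
    labs(
      x = expression(K[d] ~ (m^-1)), y = bquote(K[a] ~ (m^-1)),
      title = sprintf("%s vs Ed, 0-%g m (r = %.4f, m = %.3f)",
                      band, depth_range, st$r, st$m),
      colour = "water class"
    ) +
    theme_minimal()
}

#' @method autoplot kd_assessment
#' @export
autoplot.kd_assessment <- function(object, band = NULL, depth_range = NULL, ...) {
  ce <- object$cell_errors
  if (is.null(band)) band <- ce$band[[1]]
  if (is.null(depth_range)) depth_range <- max(ce$z_max)
  df <- filter(ce, .data$band == !!band,
               abs(.data$z_max - !!depth_range) < 1e-9)
  plot_lighting_heatmap(df, metric = "mean_abs_err_pct") +
    labs(title = sprintf("Mean |relative error| of Kd from %s, 0-%g m (%%)",
                         band, depth_range))
}
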