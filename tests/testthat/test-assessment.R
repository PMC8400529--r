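# build a tidy k_table directly (no field generation): Kd varies across
# water classes/corners, Ka bands are prescribed functions of Kd
fake_k_table <- function(ka40 = function(kd, zen, cld) 1.1 * kd,
                         ka50 = function(kd, zen, cld) 0.95 * kd,
                         zenith = seq(0, 80, 10), cloud = seq(0, 1, 0.2),
                         z_max = 1.5) {
  sc <- scenario_grid(zenith = zenith, cloud = cloud)
  kd <- 0.05 + 0.04 * sc$chl + 0.06 * sc$cdom380 + 0.02 * sc$mineral
  purrr::map_dfr(z_max, function(zm) {
    dplyr::bind_rows(
      dplyr::mutate(sc[, c("scenario_id", "water_class", "corner",
                           "solar_zenith", "cloud_fraction")],
                    band = "Ed", z_max = zm, K = kd, r_squared = 1),
      dplyr::mutate(sc[, c("scenario_id", "water_class", "corner",
                           "solar_zenith", "cloud_fraction")],
                    band = "Ea40", z_max = zm,
                    K = ka40(kd, sc$solar_zenith, sc$cloud_fraction),
                    r_squared = 1),
      dplyr::mutate(sc[, c("scenario_id", "water_class", "corner",
                           "solar_zenith", "cloud_fraction")],
                    band = "Ea50", z_max = zm,
                    K = ka50(kd, sc$solar_zenith, sc$cloud_fraction),
                    r_squared = 1)
    )
  })
}

test_that("ratio statistics aggregate scenarios per band and depth", {
  rt <- tibble::tibble(
    scenario_id = rep(c("a", "b"), each = 2),
    theta_band = rep(c(30, 40), 2),
    depth = 1.5,
    log_ratio = c(-0.5, -0.6, -0.7, -0.8)
  )
  rs <- ratio_analysis(rt)
  expect_equal(nrow(rs), 2)
  expect_equal(rs$mean_log_ratio[rs$theta_band == 30], -0.6)
  expect_equal(rs$n, c(2, 2))
  # single scenario: zero spread
  one <- ratio_analysis(rt[rt$scenario_id == "a", ])
  expect_equal(one$sd_log_ratio, c(0, 0))
  # duplicating the scenario set leaves the means unchanged
  twice <- ratio_analysis(dplyr::bind_rows(rt, rt))
  expect_equal(twice$mean_log_ratio, rs$mean_log_ratio)
  expect_error(ratio_analysis(rt, depths = 5), "requested depths")
})

test_that("scatter statistics recover exact and noisy linear relations", {
  kd <- seq(0.1, 2, length.out = 50)
  exact <- scatter_stats(kd, 1.1 * kd)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_equal(exact$m, 1.1, tolerance = 1e-12)
  expect_lt(exact$p_value, 1e-10)
  # constant response: flagged degenerate
  flat <- scatter_stats(kd, rep(1, 50))
  expect_true(is.na(flat$r))
  expect_equal(flat$m, 0)
  # seeded noise at 1% of the mean
  set.seed(97)
  noisy <- scatter_stats(kd, kd + rnorm(50, sd = 0.01 * mean(kd)))
  expect_gt(noisy$r, 0.99)
  expect_equal(noisy$m, 1, tolerance = 0.05)
  expect_error(scatter_stats(kd, kd[-1]), "equal length")
  expect_error(scatter_stats(1:2, 1:2), "3 pairs")
  expect_error(scatter_stats(rep(1, 5), 1:5), "zero variance")
})

test_that("lighting heat-maps cover the full lattice with 56-point cells", {
  kt <- fake_k_table()
  hm <- lighting_heatmaps(kt, band = "Ea40", depth_range = 1.5)
  expect_equal(nrow(hm), 9 * 6)
  expect_true(all(hm$n == 56)) # 7 classes x 8 corners
  expect_equal(hm$r, rep(1, 54), tolerance = 1e-12)
  expect_equal(hm$m, rep(1.1, 54), tolerance = 1e-12)
  expect_true(all(hm$r >= -1 & hm$r <= 1))
  # grouped and pooled paths agree when the relation is homogeneous
  pool <- annulight:::.kd_ka_pairs(kt, "Ea40", 1.5)
  global <- scatter_stats(pool$kd, pool$ka)
  expect_equal(unique(round(hm$m, 12)), round(global$m, 12))
  # a missing cell is an explicit error
  holey <- dplyr::filter(kt, !(solar_zenith == 40 & cloud_fraction == 0.4))
  expect_error(lighting_heatmaps(holey, "Ea40", 1.5), "lattice")
  expect_error(lighting_heatmaps(kt, "Ea40", 5), "depth range")
})

test_that("an exact proportional Ka yields its slope and zero error", {
  m0 <- 1.37
  kt <- fake_k_table(ka40 = function(kd, zen, cld) m0 * kd,
                     z_max = c(0.2, 1.5))
  a <- slope_and_error_tables(kt, bands = "Ea40", depth_ranges = c(0.2, 1.5))
  expect_equal(a$slope_table$m_bar, rep(m0, 2), tolerance = 1e-12)
  expect_equal(a$error_table$mean_abs_rel_error, rep(0, 2), tolerance = 1e-10)
  expect_equal(max(abs(a$cell_errors$mean_abs_err_pct)), 0, tolerance = 1e-8)
})

test_that("slope and error tables have the band-by-range layout", {
  ranges <- c(0.2, 0.5, 1, 1.5, 5, 10)
  kt <- fake_k_table(z_max = ranges)
  a <- slope_and_error_tables(kt, depth_ranges = ranges)
  expect_equal(nrow(a$slope_table), 2 * 6)
  expect_equal(nrow(a$error_table), 2 * 6)
  expect_setequal(unique(a$slope_table$band), c("Ea40", "Ea50"))
  expect_equal(nrow(a$cell_errors), 2 * 6 * 54)
  expect_error(slope_and_error_tables(kt, depth_ranges = c(1.5, 3)),
               "missing")
})

test_that("relative error is scale-free and zero at exact reconstruction", {
  # lighting-dependent slope: errors appear, but rescaling every K by a
  # constant leaves eps unchanged
  kt <- fake_k_table(
    ka40 = function(kd, zen, cld) (1 + 0.1 * (zen == 40) * (cld == 0)) * kd
  )
  a1 <- slope_and_error_tables(kt, bands = "Ea40", depth_ranges = 1.5)
  kt2 <- dplyr::mutate(kt, K = 3.7 * K)
  a2 <- slope_and_error_tables(kt2, bands = "Ea40", depth_ranges = 1.5)
  expect_equal(a1$errors$eps_pct, a2$errors$eps_pct, tolerance = 1e-10)
  expect_gt(max(a1$cell_errors$mean_abs_err_pct), 0)
})

test_that("assessment objects tidy, glance and plot", {
  kt <- fake_k_table(z_max = c(1, 1.5))
  a <- slope_and_error_tables(kt, depth_ranges = c(1, 1.5))
  td <- tidy(a)
  expect_setequal(unique(td$metric), c("mean_slope", "mean_abs_rel_error"))
  expect_equal(nrow(td), 2 * 2 * 2)
  gl <- glance(a)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("max_cell_err_Ea40", "max_cell_err_Ea50") %in% names(gl)))
  p <- ggplot2::autoplot(a)
  expect_s3_class(p, "ggplot")
  p2 <- plot_lighting_heatmap(lighting_heatmaps(kt, "Ea40", 1.5), "m")
  expect_s3_class(p2, "ggplot")
  p3 <- plot_kd_ka_scatter(kt, "Ea40", 1.5)
  expect_s3_class(p3, "ggplot")
})
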