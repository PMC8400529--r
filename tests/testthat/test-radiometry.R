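test_that("planar irradiance reproduces closed forms", {
  iso <- analytic_field(function(th, ph) 1)
  ed <- planar_ed(iso, the_grid)
  expect_equal(max(abs(ed - pi)), 0, tolerance = 1e-12) # isotropic: Ed = pi L
  # linearity
  double <- analytic_field(function(th, ph) 2)
  expect_equal(planar_ed(double, the_grid), 2 * ed, tolerance = 1e-15)
  # radiance confined to the equator band contributes mu_bar * Omega only
  eq_only <- analytic_field(function(th, ph) as.numeric(th == 87.5))
  b <- the_grid$bands
  expect_equal(planar_ed(eq_only, the_grid)[1, 1],
               b$mu_bar[10] * b$band_solid_angle[10], tolerance = 1e-12)
})

test_that("planar quadrature matches dense integration of a smooth field", {
  # L = cos(theta): exact integral over the hemisphere is 2 pi / 3
  coslobe <- analytic_field(function(th, ph) cos(th * pi / 180))
  expect_equal(planar_ed(coslobe, the_grid)[1, 1], 2 * pi / 3,
               tolerance = 0.01)
})

test_that("annular irradiance is the cosine-free band integral", {
  iso <- analytic_field(function(th, ph) 1)
  b <- the_grid$bands
  for (th in seq(10, 80, by = 10)) {
    expect_equal(annular_ea(iso, the_grid, th)[1, 1],
                 2 * pi * b$d_theta[b$theta_center == th], tolerance = 1e-12)
  }
  expect_equal(annular_ea(iso, the_grid, 40)[1, 1], 0.7040012,
               tolerance = 1e-7)
  # band selectivity
  only40 <- analytic_field(function(th, ph) as.numeric(th == 40))
  expect_gt(annular_ea(only40, the_grid, 40)[1, 1], 0)
  for (th in setdiff(seq(10, 80, 10), 40)) {
    expect_equal(annular_ea(only40, the_grid, th)[1, 1], 0)
  }
  # cap and equator are not annular measurement bands
  expect_error(annular_ea(iso, the_grid, 0), "10, 20")
  expect_error(annular_ea(iso, the_grid, 87.5), "10, 20")
  expect_error(annular_ea(iso, the_grid, 45), "10, 20")
})

test_that("planar irradiance decomposes into cosine-weighted band integrals", {
  # each theta band contributes its annular integral times a constant
  # (the band mean cosine); summing all ten reproduces Ed exactly
  sc <- pick_scenario("moderate", zenith = 40, cloud = 0.2)
  fld <- generate_field(sc, the_grid, wavelengths = c(450, 650),
                        depths = c(0.2, 1, 5))
  bi <- annulight:::.band_integrals(fld, the_grid)
  recon <- apply(sweep(bi, 2, the_grid$bands$mu_bar, "*"), c(1, 3), sum)
  expect_equal(recon, planar_ed(fld, the_grid), tolerance = 1e-12)
})

test_that("PAR integration converts band irradiance to quantum flux", {
  wl <- seq(400, 700, by = 5)
  expect_equal(par_integrate(rep(0, 61), wl), 0)
  # flat spectrum: independent oracle is the closed-form integral of
  # lambda / (h c N_A) over 400-700 nm = 1.37926e-3
  hcna <- 6.62607015e-34 * 2.99792458e8 * 6.02214076e23
  oracle <- (700e-9^2 - 400e-9^2) / 2 * 1e9 / hcna
  expect_equal(par_integrate(rep(1, 61), wl), oracle, tolerance = 1e-6)
  expect_equal(par_integrate(rep(1, 61), wl), 1.3793e-3, tolerance = 1e-4)
  # one watt concentrated in the 550 nm band
  E <- rep(0, 61)
  E[wl == 550] <- 1 / 5 # W m-2 over a 5 nm band
  expect_equal(par_integrate(E, wl), 550e-9 / hcna, tolerance = 1e-9)
  expect_equal(par_integrate(E, wl), 4.598e-6, tolerance = 1e-3)
  expect_error(par_integrate(rep(1, 2), c(390, 400)), "400-700")
  expect_error(par_integrate(rep(1, 3), c(400, 500)), "per wavelength")
})

test_that("profiles assemble Ed, Ea and their PAR reductions", {
  sc <- pick_scenario("clear", zenith = 20, cloud = 0.4)
  wl <- seq(400, 700, by = 20)
  fld <- generate_field(sc, the_grid, wavelengths = wl, depths = c(0.2, 1, 2))
  prof <- irradiance_profile(fld, the_grid)
  expect_s3_class(prof, "irradiance_profile")
  expect_equal(dim(prof$Ea), c(3, 8, length(wl)))
  expect_equal(prof$theta_bands, seq(10, 80, by = 10))
  expect_equal(prof$Ed, planar_ed(fld, the_grid))
  expect_equal(prof$Ea[, 4, ], annular_ea(fld, the_grid, 40))
  expect_equal(prof$Ed_par, par_integrate(prof$Ed, wl))
  expect_true(all(prof$Ea_par >= 0) && all(prof$Ed_par >= 0))
  # tidy export: one row per depth and band, PAR quantity
  tbl <- tibble::as_tibble(prof)
  expect_equal(nrow(tbl), 3 * 9)
  expect_setequal(unique(tbl$band), c("Ed", paste0("Ea", seq(10, 80, 10))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 27)
})

test_that("log ratio of annular to planar PAR behaves as a ratio", {
  iso <- analytic_field(function(th, ph) 1, wavelengths = c(500, 550, 600))
  prof <- irradiance_profile(iso, the_grid)
  # isotropic closed forms: log10(2 pi dtheta40 / pi)
  expect_equal(log_ratio_ea_ed(prof, 40, 0.5), log10(0.7040012 / pi),
               tolerance = 1e-6)
  expect_equal(log_ratio_ea_ed(prof, 40, 0.5), -0.6496, tolerance = 1e-4)
  expect_error(log_ratio_ea_ed(prof, 45, 0.5), "10, 20")
  expect_error(log_ratio_ea_ed(prof, 40, 0.7), "not a depth")
})
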