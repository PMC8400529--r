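test_that("scenario grid enumerates the simulation design", {
  full <- scenario_grid()
  expect_equal(nrow(full), 3024) # 7 classes x 8 corners x 9 zenith x 6 cloud
  expect_equal(nrow(scenario_grid(zenith = seq(0, 60, 10))), 2352)
  one <- scenario_grid(zenith = 30, cloud = 0.4,
                       classes = water_classes()[3, ])
  expect_equal(nrow(one), 8) # one class, all corners
  expect_equal(nrow(one[one$corner == "lohilo", ]), 1)
  # deterministic ordering and seed assignment
  again <- scenario_grid()
  expect_identical(full, again)
  expect_equal(full$seed, 12345L + seq_len(3024))
  # corner concentrations come from the class table
  uc <- full[full$water_class == "ultra clear" & full$corner == "lololo", ][1, ]
  expect_equal(c(uc$chl, uc$cdom380, uc$mineral), c(0, 0, 0))
})

test_that("scenario grid rejects empty or off-grid selections", {
  expect_error(scenario_grid(zenith = numeric(0)), "non-empty")
  expect_error(scenario_grid(classes = water_classes()[0, ]), "non-empty")
  expect_error(scenario_grid(zenith = 45), "grid")
  expect_error(scenario_grid(cloud = 0.5), "grid")
})

test_that("field generation is deterministic and non-negative", {
  sc <- pick_scenario("clear", zenith = 30, cloud = 0.2)
  wl <- seq(400, 700, by = 50)
  z <- c(0.2, 1, 3)
  f1 <- generate_field(sc, the_grid, wavelengths = wl, depths = z)
  f2 <- generate_field(sc, the_grid, wavelengths = wl, depths = z)
  expect_identical(f1$L, f2$L)
  expect_true(all(f1$L >= 0))
  # noisy fields: reproducible under the scenario seed, different otherwise
  n1 <- generate_field(sc, the_grid, wl, z, noise_sd = 0.05)
  n2 <- generate_field(sc, the_grid, wl, z, noise_sd = 0.05)
  expect_identical(n1$L, n2$L)
  sc2 <- sc
  sc2$seed <- sc$seed + 1L
  n3 <- generate_field(sc2, the_grid, wl, z, noise_sd = 0.05)
  expect_false(identical(n1$L, n3$L))
})

test_that("overcast sky gives an azimuthally uniform field", {
  sc <- pick_scenario("moderate", zenith = 30, cloud = 1)
  fld <- generate_field(sc, the_grid, wavelengths = c(450, 550),
                        depths = c(0.2, 1))
  spread <- sweep(fld$L, c(1, 2, 4), apply(fld$L, c(1, 2, 4), mean))
  expect_equal(max(abs(spread)), 0)
})

test_that("the refracted sun direction carries the brightest band", {
  # solar zenith 30 deg refracts to 21.9 deg: inside the 15-25 deg band
  sc <- pick_scenario("clear", zenith = 30, cloud = 0)
  fld <- generate_field(sc, the_grid, wavelengths = 550, depths = 0.2)
  band_sums <- apply(fld$L[1, , , 1], 1, sum)
  expect_equal(which.max(band_sums), 3L)
})

test_that("planar irradiance is log-linear in depth at each wavelength", {
  z <- depth_grid(10)
  for (class in c("ultra clear", "moderate", "very turbid")) {
    sc <- pick_scenario(class, corner = "hihihi", zenith = 50, cloud = 0.4)
    fld <- generate_field(sc, the_grid, wavelengths = c(450, 550, 650),
                          depths = z)
    ed <- planar_ed(fld, the_grid)
    for (j in seq_len(ncol(ed))) {
      r2 <- stats::cor(z, log(ed[, j]))^2
      expect_gt(r2, 0.999)
    }
  }
})

test_that("regression K recovers the generator ground truth per wavelength", {
  z <- depth_grid(10)
  wl <- seq(400, 700, by = 50)
  for (class in c("ultra clear", "clear", "turbid")) {
    for (cloud in c(0, 0.6)) {
      sc <- pick_scenario(class, corner = "hihilo", zenith = 40, cloud = cloud)
      fld <- generate_field(sc, the_grid, wavelengths = wl, depths = z)
      ed <- planar_ed(fld, the_grid)
      k_fit <- vapply(seq_along(wl),
                      function(j) k_regression(z, ed[, j])$K, numeric(1))
      expect_equal(k_fit, fld$kd_true$kd_true, tolerance = 0.03)
    }
  }
})

test_that("the direct beam stays inside Snell's window in clear water", {
  # direct-only fields (f_dif = 0): the energy in bands with lower edge
  # >= 55 deg stays under 5% at 0.2 m for any solar zenith angle when
  # scattering is weak (sigma barely broadened at that depth)
  lower <- the_grid$bands$theta_lower
  for (class in c("ultra clear", "very clear")) {
    for (zen in seq(0, 80, by = 10)) {
      sc <- pick_scenario(class, zenith = zen, cloud = 0)
      fld <- generate_field(sc, the_grid, wavelengths = 550, depths = 0.2,
                            f_dif = 0)
      bi <- annulight:::.band_integrals(fld, the_grid)
      frac <- sum(bi[1, lower >= 55, 1]) / sum(bi[1, , 1])
      expect_lt(frac, 0.05)
    }
  }
})

test_that("radiance fields roundtrip through the container format", {
  sc <- pick_scenario("very clear", zenith = 20, cloud = 0.4)
  fld <- generate_field(sc, the_grid, wavelengths = c(500, 600),
                        depths = c(0.5, 1, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  write_radiance_field(fld, path)
  back <- read_radiance_field(path)
  expect_identical(back$L, fld$L)
  expect_identical(back$scenario, fld$scenario)
  expect_identical(back$kd_true, fld$kd_true)
  # malformed container: mismatched depth coordinate is named
  bad <- fld
  bad$depths <- bad$depths[-1]
  saveRDS(bad, path)
  expect_error(read_radiance_field(path), "depth")
  expect_error(read_radiance_field(tempfile()), "No such file")
})

test_that("band-sum export counts the polar cap once", {
  fld <- analytic_field(function(th, ph) 1)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_band_sums(fld, path)
  cap <- out[out$theta_center == 0, ]
  expect_equal(unique(cap$band_radiance_sum), 1) # 24 replicated slots / 24
  band40 <- out[out$theta_center == 40, ]
  expect_equal(unique(band40$band_radiance_sum), 24)
  expect_true(file.exists(path))
})
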