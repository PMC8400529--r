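# Shared fixtures: all built in code, no stored data.

the_grid <- build_grid()

# hand-built radiance field with a prescribed per-quad radiance function
# f(theta_center_deg, phi_center_deg); constant over depth and wavelength
analytic_field <- function(f, depths = c(0.5, 1.5), wavelengths = c(500, 600),
                           grid = the_grid) {
  th <- grid$bands$theta_center
  ph <- seq(7.5, 352.5, by = 15)
  slab <- outer(th, ph, Vectorize(f))
  arr <- aperm(
    array(slab, dim = c(10, 24, length(depths), length(wavelengths))),
    c(3, 1, 2, 4)
  )
  structure(
    list(
      L = arr, depths = depths, wavelengths = wavelengths,
      theta_centers = th, phi_centers = ph, kd_true = NULL,
      scenario = tibble::tibble(
        scenario_id = "analytic", water_class = NA_character_,
        corner = NA_character_, chl = 0, cdom380 = 0, mineral = 0,
        solar_zenith = 0, cloud_fraction = 0, seed = 1L, noise_sd = 0
      )
    ),
    class = "radiance_field"
  )
}

# a single scenario row picked out of the standard grid
pick_scenario <- function(class, corner = "lololo", zenith = 30, cloud = 0.2) {
  sc <- scenario_grid(zenith = zenith, cloud = cloud)
  sc[sc$water_class == class & sc$corner == corner, ][1, ]
}

# independent solid-angle oracle: dense numerical integration of
# sin(theta) over the quad
oracle_solid_angle <- function(theta_lo, theta_hi, dphi_rad, n = 20000) {
  th <- seq(theta_lo, theta_hi, length.out = n) * pi / 180
  mid <- (th[-1] + th[-n]) / 2
  sum(sin(mid) * diff(th)) * dphi_rad
}
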