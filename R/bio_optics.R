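# Bio-optical model: constituent concentrations -> inherent optical
# properties (IOPs) and a two-stream ground-truth attenuation for the
# synthetic generator. The parameterization is a deliberately simple
# case-2-water model: chlorophyll-driven phytoplankton absorption with the
# usual blue (440 nm) and red (675 nm) peaks, CDOM with an exponential
# spectral slope referenced at 380 nm, mineral absorption referenced at
# 443 nm, and 1/lambda particulate scattering.

# pure-water absorption (m-1), 400-700 nm at 10 nm, standard published
# clear-natural-water values; interpolated linearly to finer grids
.aw_table <- list(
  wavelength = seq(400, 700, by = 10),
  a = c(
    0.00663, 0.00473, 0.00454, 0.00495, 0.00635, 0.00922, 0.00979, 0.0106,
    0.0127, 0.0150, 0.0204, 0.0325, 0.0409, 0.0434, 0.0474, 0.0565,
    0.0619, 0.0695, 0.0896, 0.1351, 0.2224, 0.2644, 0.2755, 0.2916,
    0.3108, 0.340, 0.410, 0.439, 0.465, 0.516, 0.624
  )
)

# fixed model constants
.biopt <- list(
  s_cdom = 0.014,   # CDOM spectral slope, nm-1, referenced at 380 nm
  a_star_min = 0.03, # mineral specific absorption at 443 nm, m2 g-1
  s_min = 0.011,    # mineral spectral slope, nm-1
  b_star_ph = 0.30, # phytoplankton specific scattering at 550 nm, m2 mg-1
  b_star_min = 0.50, # mineral specific scattering at 550 nm, m2 g-1
  bb_ratio = 0.018, # particulate backscatter ratio
  mu_dif = 0.83,    # mean cosine of the in-water diffuse stream
  sky_dif = 0.15    # clear-sky diffuse fraction (skylight with no cloud)
)

.aw <- function(wavelengths) {
  stats::approx(.aw_table$wavelength, .aw_table$a, xout = wavelengths,
                rule = 2)$y
}

.bw <- function(wavelengths) {
  # molecular scattering with the standard lambda^-4.32 shape
  0.00288 * (500 / wavelengths)^4.32
}

.a_star_ph <- function(wavelengths) {
  0.05 * (exp(-(wavelengths - 440)^2 / (2 * 30^2)) +
            0.6 * exp(-(wavelengths - 675)^2 / (2 * 20^2)))
}

#' The seven reference water classes
#'
#' Optical water classes spanning ultra clear to brown (humic) waters, each
#' defined by low/high concentrations of chlorophyll (mg m-3), CDOM
#' absorption at 380 nm (m-1) and suspended minerals (g m-3). The
#' concentration pairs are treated as unordered \{low, high\} sets, so
#' `*_lo <= *_hi` always holds.
#'
#' @return a tibble with columns `water_class`, `chl_lo`, `chl_hi`,
#'   `cdom_lo`, `cdom_hi`, `mineral_lo`, `mineral_hi`.
#' @examples
#' water_classes()
#' @export
water_classes <- function() {
  tibble::tribble(
    ~water_class, ~chl_lo, ~chl_hi, ~cdom_lo, ~cdom_hi, ~mineral_lo, ~mineral_hi,
    "ultra clear",  0.0,  1.0,  0.0,  0.6,  0.0,  0.8,
    "very clear",   1.0,  3.0,  0.5,  1.5,  0.5,  1.5,
    "clear",        2.1,  7.5,  1.3,  3.3,  1.2,  2.4,
    "moderate",     3.9, 17.1,  5.0, 12.0,  1.0,  6.6,
    "turbid",      19.7, 41.3,  5.5,  9.7, 10.8, 18.6,
    "very turbid", 65.2, 67.6,  6.1,  6.7, 30.3, 38.7,
    "brown",        3.3, 20.3, 18.1, 22.5,  2.2,  7.8
  )
}

#' Write / read the water-class table as CSV
#'
#' @param path file path.
#' @param classes a water-class tibble (defaults to [water_classes()]).
#' @return `write_water_classes()` returns `path` invisibly;
#'   `read_water_classes()` returns the tibble.
#' @export
write_water_classes <- function(path, classes = water_classes()) {
  readr::write_csv(classes, path)
  invisible(path)
}

#' @rdname write_water_classes
#' @export
read_water_classes <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Inherent optical properties for a constituent mix
#'
#' Evaluates the package's parametric case-2 bio-optical model:
#' \deqn{a(\lambda) = a_w + chl \, a^*_{ph}(\lambda) +
#'   cdom_{380} e^{-S_g (\lambda - 380)} + mineral \, a^*_m e^{-S_m (\lambda - 443)}}
#' \deqn{b(\lambda) = b_w + (chl \, b^*_{ph} + mineral \, b^*_m)(550/\lambda)}
#' with backscattering \eqn{b_b = B_b (b - b_w) + 0.5 b_w}.
#'
#' @param chl chlorophyll concentration, mg m-3.
#' @param cdom380 CDOM absorption at 380 nm, m-1.
#' @param mineral suspended mineral concentration, g m-3.
#' @param wavelengths wavelength grid in nm (default 400-700 at 5 nm).
#' @return a tibble with columns `wavelength`, `a`, `b`, `bb` (all m-1).
#' @examples
#' iops(chl = 5, cdom380 = 1, mineral = 0.5)
#' @export
iops <- function(chl, cdom380, mineral, wavelengths = seq(400, 700, by = 5)) {
  if (any(c(chl, cdom380, mineral) < 0)) {
    abort("Constituent concentrations must be >= 0.")
  }
  aw <- .aw(wavelengths)
  bw <- .bw(wavelengths)
  a <- aw +
    chl * .a_star_ph(wavelengths) +
    cdom380 * exp(-.biopt$s_cdom * (wavelengths - 380)) +
    mineral * .biopt$a_star_min * exp(-.biopt$s_min * (wavelengths - 443))
  b <- bw + (chl * .biopt$b_star_ph + mineral * .biopt$b_star_min) *
    (550 / wavelengths)
  bb <- .biopt$bb_ratio * (b - bw) + 0.5 * bw
  tibble::tibble(wavelength = wavelengths, a = a, b = b, bb = bb)
}

#' Refraction of a zenith angle across a flat air-water interface
#'
#' Snell's law with water refractive index n = 1.34: an above-surface
#' zenith angle maps to the in-water angle asin(sin(theta)/n). The whole
#' sky folds into Snell's window, a cone of half-angle about 48.3 degrees.
#'
#' @param theta_air above-surface zenith angle(s), degrees, in 0..90.
#' @return in-water zenith angle(s), degrees.
#' @examples
#' snell_refract(c(0, 40, 90))
#' @export
snell_refract <- function(theta_air) {
  if (any(theta_air < 0 | theta_air > 90)) {
    abort("`theta_air` must lie in [0, 90] degrees.")
  }
  asin(sin(theta_air * pi / 180) / .const$n_water) * 180 / pi
}

# diffuse fraction of surface irradiance: clear-sky skylight plus cloud
.diffuse_fraction <- function(cloud_fraction) {
  pmin(1, cloud_fraction + .biopt$sky_dif * (1 - cloud_fraction))
}

#' Ground-truth diffuse attenuation of the synthetic generator
#'
#' The two-stream reference attenuation the radiance generator is built to
#' decay with: \eqn{K_d = (a + b_b)/\mu_{eff}} with effective mean cosine
#' \eqn{\mu_{eff} = (1 - f_{dif}) \cos\theta_{sw} + f_{dif}\,\mu_{dif}},
#' where \eqn{\theta_{sw}} is the refracted solar zenith angle,
#' \eqn{\mu_{dif} = 0.83} the diffuse-stream mean cosine, and the diffuse
#' fraction is \eqn{f_{dif} = \min(1, cloud + 0.15(1 - cloud))}.
#'
#' @param iops an [iops()] tibble.
#' @param theta_air solar zenith angle above the surface, degrees.
#' @param cloud_fraction cloud cover in 0..1.
#' @param f_dif optional explicit diffuse fraction overriding the
#'   cloud-cover mapping (used to probe the pure-direct limit `f_dif = 0`).
#' @return a tibble `wavelength`, `kd_true` (m-1).
#' @examples
#' ground_truth_kd(iops(1, 0.5, 0.2), theta_air = 30, cloud_fraction = 0.2)
#' @export
ground_truth_kd <- function(iops, theta_air, cloud_fraction, f_dif = NULL) {
  stopifnot(all(c("wavelength", "a", "bb") %in% names(iops)))
  if (is.null(f_dif)) f_dif <- .diffuse_fraction(cloud_fraction)
  theta_sw <- snell_refract(theta_air)
  mu_eff <- (1 - f_dif) * cos(theta_sw * pi / 180) + f_dif * .biopt$mu_dif
  tibble::tibble(
    wavelength = iops$wavelength,
    kd_true = (iops$a + iops$bb) / mu_eff
  )
}
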