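# Angular discretization of the downward hemisphere.
#
# The sphere of directions is cut into "quads": polar-angle (theta) bands
# crossed with azimuth (phi) bins. theta is measured from the downward
# vertical, so the downward hemisphere is theta in [0, 90] deg. The fixed
# scheme used everywhere in this package is the radiative-transfer standard:
# a polar cap (0-5 deg, one quad spanning all azimuths), eight 10-degree
# bands from 5-15 up to 75-85 deg, an equator band (85-90 deg), and 24
# azimuth bins of 15 deg each for every band except the cap.

#' Build the standard quad grid for the downward hemisphere
#'
#' Constructs the fixed angular discretization used by all irradiance
#' integrations: theta band edges \{0, 5, 15, ..., 85, 90\} degrees and 24
#' azimuth bins of 15 degrees. The polar cap (0-5 deg) is a single quad with
#' no azimuthal subdivision; all other bands have 24 quads.
#'
#' For each band the grid stores the polar thickness
#' \eqn{d\theta_i = \cos\theta_{lower} - \cos\theta_{upper}} (so that
#' \eqn{d\theta_i \, d\phi_j} is the quad solid angle in steradians) and the
#' exact band mean cosine
#' \eqn{\bar\mu_i = (\cos^2\theta_{lower} - \cos^2\theta_{upper}) / (2\, d\theta_i)},
#' the weight that makes cosine-weighted (planar) integration exact for
#' radiance that is constant within a band; with it an isotropic radiance L
#' integrates to exactly \eqn{\pi L}.
#'
#' @return An object of class `quad_grid`: a list with
#'   \describe{
#'     \item{bands}{tibble with one row per theta band: `band_index`,
#'       `theta_lower`, `theta_upper`, `theta_center` (degrees), `n_phi`,
#'       `d_theta`, `mu_bar`, `band_solid_angle` (sr, summed over the band's
#'       phi bins), `quad_solid_angle` (sr, one quad), `annular` (logical:
#'       is this one of the eight 10-80 deg measurement bands).}
#'     \item{phi_edges}{azimuth bin edges in degrees, 0 to 360 by 15.}
#'     \item{d_phi}{azimuth bin width in radians, 2 pi / 24.}
#'   }
#' @examples
#' grid <- build_grid()
#' grid$bands
#' sum(grid$bands$band_solid_angle) # 2 pi
#' @export
build_grid <- function() {
  lower <- c(0, seq(5, 85, by = 10))
  upper <- c(5, seq(15, 85, by = 10), 90)
  center <- c(0, seq(10, 80, by = 10), 87.5)
  n_phi <- c(1L, rep(24L, 9))
  d_phi <- 2 * pi / 24

  cl <- cos(lower * pi / 180)
  cu <- cos(upper * pi / 180)
  d_theta <- cl - cu
  mu_bar <- (cl^2 - cu^2) / (2 * d_theta)
  # cap: single quad spanning all azimuths; others: d_theta * d_phi per quad
  quad_sa <- ifelse(n_phi == 1L, 2 * pi * d_theta, d_theta * d_phi)
  band_sa <- quad_sa * n_phi

  bands <- tibble::tibble(
    band_index = seq_along(lower),
    theta_lower = lower,
    theta_upper = upper,
    theta_center = center,
    n_phi = n_phi,
    d_theta = d_theta,
    mu_bar = mu_bar,
    quad_solid_angle = quad_sa,
    band_solid_angle = band_sa,
    annular = center %in% seq(10, 80, by = 10)
  )

  structure(
    list(bands = bands, phi_edges = seq(0, 360, by = 15), d_phi = d_phi),
    class = "quad_grid"
  )
}

#' Solid angle of one quad
#'
#' Returns the solid angle, in steradians, of the quad at a given theta band
#' and phi bin: \eqn{d\theta_i \, d\phi_j} for ordinary quads and
#' \eqn{2\pi(1 - \cos 5^\circ)} for the polar cap, which has no azimuthal
#' subdivision (its `phi_index` must be 1).
#'
#' @param grid a [build_grid()] object.
#' @param band_index integer theta-band index, 1 (cap) to 10 (equator band).
#' @param phi_index integer azimuth bin index, 1 to 24 (1 for the cap).
#' @return solid angle in steradians.
#' @examples
#' grid <- build_grid()
#' quad_solid_angle(grid, band_index = 5, phi_index = 1)
#' quad_solid_angle(grid, band_index = 1, phi_index = 1) # polar cap
#' @export
quad_solid_angle <- function(grid, band_index, phi_index) {
  stopifnot(inherits(grid, "quad_grid"))
  nb <- nrow(grid$bands)
  if (!is.numeric(band_index) || length(band_index) != 1 ||
      band_index < 1 || band_index > nb || band_index != round(band_index)) {
    abort(sprintf("`band_index` must be an integer in 1..%d.", nb))
  }
  np <- grid$bands$n_phi[[band_index]]
  if (!is.numeric(phi_index) || length(phi_index) != 1 ||
      phi_index < 1 || phi_index > np || phi_index != round(phi_index)) {
    abort(sprintf(
      "`phi_index` must be an integer in 1..%d for band %d.", np, band_index
    ))
  }
  grid$bands$quad_solid_angle[[band_index]]
}

#' @export
print.quad_grid <- function(x, ...) {
  cat("<quad_grid> downward hemisphere,", nrow(x$bands), "theta bands x 24 phi bins\n")
  cat("  phi bin width:", format(x$d_phi, digits = 6), "rad\n")
  cat("  total solid angle:", format(sum(x$bands$band_solid_angle), digits = 10), "sr\n")
  print(x$bands, ...)
  invisible(x)
}

#' Tabulate a quad grid
#'
#' One row per theta band, suitable for CSV export and inspection.
#'
#' @param x a `quad_grid`.
#' @param ... unused.
#' @return a tibble (the `bands` table).
#' @method as_tibble quad_grid
#' @export
as_tibble.quad_grid <- function(x, ...) x$bands

#' Write a quad grid to CSV
#'
#' @param grid a `quad_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quad_grid <- function(grid, path) {
  stopifnot(inherits(grid, "quad_grid"))
  readr::write_csv(grid$bands, path)
  invisible(path)
}

# Internal: per-quad planar (cosine) weights and annular weights as
# band x phi matrices aligned with the radiance array layout. The cap's
# single quad is represented by 24 identical array slots, so its weight is
# spread as quad_solid_angle / 24 per slot (the radiance is replicated, so
# the band total is exact).
.quad_weights <- function(grid) {
  b <- grid$bands
  per_slot <- b$quad_solid_angle
  per_slot[b$n_phi == 1L] <- per_slot[b$n_phi == 1L] / 24
  planar <- matrix(per_slot * b$mu_bar, nrow = nrow(b), ncol = 24)
  ann <- matrix(per_slot, nrow = nrow(b), ncol = 24)
  list(planar = planar, annular = ann)
}
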