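# Integration of quad-gridded radiance into irradiances.
#
# Planar downwelling irradiance Ed is the cosine-weighted integral of
# radiance over the downward hemisphere; annular irradiance Ea(theta_i) is
# the radiance of one theta band integrated over all azimuths with no
# cosine factor (the sensor ring is normal to the theta direction). Both
# are reduced to PAR (400-700 nm quantum flux) for the attenuation
# analyses.

#' Planar downwelling irradiance from a radiance field
#'
#' \eqn{E_d(z, \lambda) = \sum_{quads} L \,\bar\mu_{band}\, \Omega_{quad}},
#' using the exact band mean-cosine weights of the quad grid, so an
#' isotropic radiance L gives exactly \eqn{\pi L}.
#'
#' @param field a [generate_field()] radiance field (or any
#'   `radiance_field` on the standard grid).
#' @param grid the [build_grid()] discretization the field lives on.
#' @return matrix of irradiance (W m-2 nm-1), depths in rows, wavelengths
#'   in columns.
#' @export
planar_ed <- function(field, grid) {
  w <- .match_field_grid(field, grid)$planar
  .contract_quads(field$L, as.vector(w))
}

#' Annular irradiance of one theta band
#'
#' \eqn{E_a(\theta_i) = \sum_{j=1}^{24} L(\theta_i, \phi_j)\, d\theta_i\, d\phi_j}:
#' the band's radiance summed over its 24 azimuth quads weighted by the
#' quad solid angles, with no cosine factor. Defined for the eight
#' measurement bands centred at 10, 20, ..., 80 degrees only (the polar
#' cap and the equator band are not annular measurement bands).
#'
#' @inheritParams planar_ed
#' @param theta_center centre of the annular band in degrees; one of
#'   `seq(10, 80, 10)`.
#' @return matrix of band irradiance (W m-2 nm-1), depths x wavelengths.
#' @export
annular_ea <- function(field, grid, theta_center) {
  .match_field_grid(field, grid)
  if (length(theta_center) != 1 || !theta_center %in% seq(10, 80, by = 10)) {
    abort("`theta_center` must be one of 10, 20, ..., 80 degrees.")
  }
  b <- match(theta_center, grid$bands$theta_center)
  sa <- grid$bands$quad_solid_angle[[b]]
  d <- dim(field$L)
  m <- matrix(aperm(field$L[, b, , , drop = FALSE], c(1, 4, 3, 2)),
              d[1] * d[4], d[3])
  matrix(rowSums(m) * sa, nrow = d[1], ncol = d[4])
}

# check field/grid compatibility, return quad weights
.match_field_grid <- function(field, grid) {
  stopifnot(inherits(field, "radiance_field"), inherits(grid, "quad_grid"))
  d <- dim(field$L)
  if (d[2] != nrow(grid$bands) || d[3] != 24 ||
      !isTRUE(all.equal(field$theta_centers, grid$bands$theta_center))) {
    abort("Radiance field and quad grid have mismatched angular layouts.")
  }
  .quad_weights(grid)
}

# contract the (z, band, phi, lambda) array against per-quad weights
.contract_quads <- function(L, w_vec) {
  d <- dim(L)
  m <- matrix(aperm(L, c(1, 4, 2, 3)), d[1] * d[4], d[2] * d[3])
  matrix(m %*% w_vec, nrow = d[1], ncol = d[4])
}

# all-band integrals (cap and equator included), no cosine: z x band x lambda
.band_integrals <- function(field, grid) {
  wts <- .match_field_grid(field, grid)
  d <- dim(field$L)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (b in seq_len(d[2])) {
    m <- matrix(aperm(field$L[, b, , , drop = FALSE], c(1, 4, 3, 2)),
                d[1] * d[4], d[3])
    out[, b, ] <- matrix(m %*% wts$annular[b, ], nrow = d[1])
  }
  out
}

#' Integrate a spectrum to PAR quantum flux
#'
#' Rectangle band sum of \eqn{E(\lambda)\, \lambda / (h c N_A)} over the
#' 400-700 nm range: each grid point contributes its band width (taken
#' from the grid spacing, so the two end points carry half-width bands)
#' times the quanta-per-joule factor at the band-centre wavelength.
#'
#' @param E spectral irradiance in W m-2 nm-1: a vector over `wavelengths`,
#'   or a matrix with one row per depth and one column per wavelength.
#' @param wavelengths wavelength grid in nm; must lie within 400-700 nm.
#' @return PAR in mol quanta s-1 m-2 (scalar, or vector per row of `E`).
#' @examples
#' par_integrate(rep(1, 61), seq(400, 700, 5))
#' @export
par_integrate <- function(E, wavelengths) {
  if (any(wavelengths < 400 - 1e-9 | wavelengths > 700 + 1e-9)) {
    abort("PAR integration requires wavelengths within 400-700 nm.")
  }
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  if (ncol(E) != length(wavelengths)) {
    abort("`E` must have one column (or element) per wavelength.")
  }
  q <- .par_quanta_weights(wavelengths)
  drop(E %*% q)
}

.par_quanta_weights <- function(wavelengths) {
  n <- length(wavelengths)
  if (n == 1) {
    dl <- 1
  } else {
    edges <- c(wavelengths[1], (wavelengths[-n] + wavelengths[-1]) / 2,
               wavelengths[n])
    dl <- diff(edges)
  }
  dl * (wavelengths * 1e-9) / (.const$planck * .const$c_light * .const$avogadro)
}

#' Irradiance profile of a radiance field
#'
#' Integrates a radiance field into the full profile used by the
#' attenuation analyses: spectral Ed and Ea for the eight annular bands,
#' plus their PAR reductions.
#'
#' @inheritParams planar_ed
#' @return an object of class `irradiance_profile`: list with `depths`,
#'   `wavelengths`, `theta_bands` (10-80 deg), `Ed` (depth x wavelength),
#'   `Ea` (depth x band x wavelength), `Ed_par` (per depth), `Ea_par`
#'   (depth x band) and the originating `scenario` row.
#' @examples
#' grid <- build_grid()
#' sc <- scenario_grid(zenith = 30, cloud = 0.2)[1, ]
#' fld <- generate_field(sc, grid, wavelengths = seq(400, 700, 20),
#'                       depths = depth_grid(1.5))
#' prof <- irradiance_profile(fld, grid)
#' head(prof$Ed_par)
#' @export
irradiance_profile <- function(field, grid) {
  ed <- planar_ed(field, grid)
  ann_idx <- which(grid$bands$annular)
  all_bands <- .band_integrals(field, grid)
  ea <- all_bands[, ann_idx, , drop = FALSE]
  q <- .par_quanta_weights(field$wavelengths)
  d <- dim(ea)
  ea_par <- matrix(matrix(ea, d[1] * d[2], d[3]) %*% q, nrow = d[1])
  structure(
    list(
      depths = field$depths,
      wavelengths = field$wavelengths,
      theta_bands = grid$bands$theta_center[ann_idx],
      Ed = ed,
      Ea = ea,
      Ed_par = drop(ed %*% q),
      Ea_par = ea_par,
      scenario = field$scenario
    ),
    class = "irradiance_profile"
  )
}

#' @export
print.irradiance_profile <- function(x, ...) {
  cat("<irradiance_profile>",
      if (!is.null(x$scenario)) x$scenario$scenario_id else "", "\n")
  cat(sprintf(
    "  %d depths (%.2f-%.2f m), %d wavelengths, annular bands %s deg\n",
    length(x$depths), min(x$depths), max(x$depths), length(x$wavelengths),
    paste(range(x$theta_bands), collapse = "-")
  ))
  invisible(x)
}

#' Tidy view of an irradiance profile (PAR quantities)
#'
#' @param x an `irradiance_profile`.
#' @param ... unused.
#' @return tibble with `scenario_id`, `depth`, `band` (`"Ed"` or
#'   `"Ea10"`..`"Ea80"`), `quantity` (`"PAR"`), `value`.
#' @method as_tibble irradiance_profile
#' @export
as_tibble.irradiance_profile <- function(x, ...) {
  sid <- if (!is.null(x$scenario)) x$scenario$scenario_id else NA_character_
  bands <- c("Ed", paste0("Ea", x$theta_bands))
  vals <- cbind(x$Ed_par, x$Ea_par)
  tibble::tibble(
    scenario_id = sid,
    depth = rep(x$depths, times = length(bands)),
    band = rep(bands, each = length(x$depths)),
    quantity = "PAR",
    value = as.vector(vals)
  )
}

#' Write an irradiance profile as tidy CSV
#'
#' @param profile an `irradiance_profile`.
#' @param path output CSV path.
#' @return the tibble written, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- as_tibble(profile)
  readr::write_csv(out, path)
  invisible(out)
}

#' Log-ratio of annular to planar PAR irradiance
#'
#' \eqn{\log_{10}(E_a(\theta_i)/E_d)} of the PAR-integrated irradiances at
#' one depth: the quantity used to select the optimal annular angle (high
#' values mean the ring captures much of the available light).
#'
#' @param profile an [irradiance_profile()].
#' @param theta_center annular band centre, degrees (10..80).
#' @param z depth in metres; must be one of the profile's depths.
#' @return dimensionless log10 ratio.
#' @export
log_ratio_ea_ed <- function(profile, theta_center, z) {
  stopifnot(inherits(profile, "irradiance_profile"))
  b <- match(theta_center, profile$theta_bands)
  if (is.na(b)) abort("`theta_center` must be one of 10, 20, ..., 80 degrees.")
  iz <- which(abs(profile$depths - z) < 1e-9)
  if (length(iz) != 1) abort("`z` is not a depth of this profile.")
  ed <- profile$Ed_par[iz]
  if (ed <= 0) abort("Ed is zero at this depth; the ratio is undefined.")
  log10(profile$Ea_par[iz, b] / ed)
}
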