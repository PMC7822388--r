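# Built-in material table.
#
# mu (1/cm) and delta (dimensionless) for the tabulated working energies.
# Provenance:
#   * water, PTFE, PMMA, LDPE: mu(20 keV), mu(12 keV) and delta(20 keV) are
#     monochromatic values for the pure compounds as served by standard X-ray
#     optics tables (XOP-type compilations); mu(30 keV) for water and PMMA
#     from the same source family.
#   * delta at 12 and 30 keV is derived from delta(20 keV) by the exact
#     far-from-edge scaling delta ~ 1/E^2.
#   * bone (cortical): mu/rho = 4.001 cm^2/g at 20 keV (NIST XCOM, cortical
#     bone ICRU-44), rho = 1.92 g/cm^3; delta from the electron density
#     rho_e = 5.95e23 cm^-3 via delta = r0 lambda^2 rho_e / (2 pi).
#     mu at 12/30 keV log-log interpolated from the same NIST table.
#   * polyethylene (tube wall): LDPE values scaled by the density ratio
#     0.94/0.92.
# Compositions are formula units (atomic number, atom count); densities g/cm^3.

.delta_scale_E <- function(d20, E) d20 * (20 / E)^2

.materials <- local({
  comp <- function(Z, n) data.frame(Z = Z, n = n)
  list(
    water = list(
      density = 1.00, composition = comp(c(1, 8), c(2, 1)),
      mu = c(`12` = 2.729, `20` = 0.7369, `30` = 0.376),
      delta20 = 5.653e-7),
    PTFE = list(
      density = 2.20, composition = comp(c(6, 9), c(2, 4)),
      mu = c(`12` = 6.776, `20` = 1.907),
      delta20 = 1.039e-6),
    PMMA = list(
      density = 1.18, composition = comp(c(6, 1, 8), c(5, 8, 2)),
      mu = c(`12` = 2.111, `20` = 0.6280, `30` = 0.362),
      delta20 = 6.777e-7),
    LDPE = list(
      density = 0.92, composition = comp(c(6, 1), c(2, 4)),
      mu = c(`12` = 1.195, `20` = 0.3905),
      delta20 = 5.863e-7),
    polyethylene = list(
      density = 0.94, composition = comp(c(6, 1), c(2, 4)),
      mu = c(`12` = 1.195, `20` = 0.3905, `30` = NA) * (0.94 / 0.92),
      delta20 = 5.863e-7 * (0.94 / 0.92)),
    bone = list(
      density = 1.92, composition = comp(c(20, 15, 8, 1), c(5, 3, 13, 1)),
      mu = c(`12` = 32.6, `20` = 7.682, `30` = 2.556),
      delta20 = 1.026e-6)
  )
})

#' Look up tabulated optical properties of a built-in material
#'
#' Returns the linear absorption coefficient `mu` (1/cm) and refractive-index
#' decrement `delta` at one of the tabulated working energies, together with
#' the elemental composition and mass density used by the quantification
#' layer.  `delta` at 12 and 30 keV is derived from the 20 keV value by the
#' exact `1/E^2` scaling (valid away from absorption edges).
#'
#' @param name one of `"water"`, `"PTFE"`, `"PMMA"`, `"LDPE"`, `"bone"`,
#'   `"polyethylene"`.
#' @param energy photon energy in keV; one of 12, 20, 30 (not every material
#'   is tabulated at every energy).
#' @return An object of class `material_spec`: a list with elements `name`,
#'   `energy` (keV), `mu` (1/cm), `delta`, `beta` (imaginary part of the
#'   refractive index, `lambda * mu / 4 pi`), `wavelength` (cm),
#'   `composition` (data frame with columns `Z`, `n`) and `density` (g/cm^3).
#' @examples
#' material_lookup("water", 20)$mu    # 0.7369
#' material_lookup("PTFE", 12)$mu     # 6.776
#' @export
material_lookup <- function(name, energy) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.materials))
    stop("unknown material '", paste(name, collapse = ","),
         "'; available: ", paste(names(.materials), collapse = ", "),
         call. = FALSE)
  m <- .materials[[name]]
  key <- as.character(energy)
  if (length(energy) != 1L || !key %in% names(m$mu) || is.na(m$mu[[key]]))
    stop("material '", name, "' is not tabulated at ", energy,
         " keV; available energies: ",
         paste(names(m$mu)[!is.na(m$mu)], collapse = ", "), " keV",
         call. = FALSE)
  lambda <- .hc / energy
  delta <- .delta_scale_E(m$delta20, energy)
  structure(list(
    name = name, energy = energy, mu = unname(m$mu[[key]]), delta = delta,
    beta = lambda * unname(m$mu[[key]]) / (4 * pi), wavelength = lambda,
    composition = m$composition, density = m$density
  ), class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s at %g keV: mu = %.4g /cm, delta = %.4g\n",
              x$name, x$energy, x$mu, x$delta))
  invisible(x)
}

#' Names of the built-in materials
#' @return Character vector of material names accepted by
#'   [material_lookup()].
#' @export
list_materials <- function() names(.materials)

#' Electron density of a built-in material
#'
#' Computed from the mass density and elemental composition:
#' `rho_e = rho * N_A * sum(n_j Z_j) / sum(n_j A_j)`.
#'
#' @param name built-in material name.
#' @return Electron density in electrons per cm^3.
#' @export
electron_density <- function(name) {
  m <- .materials[[name]]
  if (is.null(m)) stop("unknown material '", name, "'", call. = FALSE)
  A <- .atomic_mass(m$composition$Z)
  m$density * .NA_AVOGADRO * sum(m$composition$n * m$composition$Z) /
    sum(m$composition$n * A)
}

# Standard atomic weights for the elements appearing in the bundled
# compositions (IUPAC 2021 abridged).
.atomic_mass <- function(Z) {
  tab <- c(`1` = 1.008, `6` = 12.011, `7` = 14.007, `8` = 15.999,
           `9` = 18.998, `15` = 30.974, `20` = 40.078)
  out <- tab[as.character(Z)]
  if (anyNA(out)) stop("no atomic mass tabulated for Z = ",
                       paste(Z[is.na(out)], collapse = ", "), call. = FALSE)
  unname(out)
}
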