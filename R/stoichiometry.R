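#' Stoichiometry conversion constants
#'
#' Constants used to convert measured geometry (map volume, filament
#' length, growth rate) into molecular mass and Abeta monomer counts:
#' a map-density to mass conversion of 825 Da per cubic Angstrom, a
#' cross-beta strand rise of 0.48 nm per monomer, and the average
#' monomer mass of Abeta42 ([AB42_MONOMER_MASS_DA]).  With
#' `core_only = TRUE` the monomer mass of the ordered core (residues
#' 15-42, [AB42_CORE_MASS_DA]) is used instead, for maps in which the
#' disordered N-terminus contributes no density.
#'
#' @param density_conversion Da per cubic nm.
#' @param strand_rise_nm nm of filament length per monomer.
#' @param monomer_mass_da Monomer mass in Da; defaults to the package
#'   Abeta42 constant.
#' @param core_only Use the residues 15-42 core mass.
#' @return List of class `stoich_constants`.
#' @export
stoich_constants <- function(density_conversion = 825,
                             strand_rise_nm = 0.48,
                             monomer_mass_da = NULL,
                             core_only = FALSE) {
  if (is.null(monomer_mass_da))
    monomer_mass_da <- if (core_only) AB42_CORE_MASS_DA else AB42_MONOMER_MASS_DA
  stopifnot(density_conversion > 0, strand_rise_nm > 0,
            monomer_mass_da > 0)
  structure(list(density_conversion = density_conversion,
                 strand_rise_nm = strand_rise_nm,
                 monomer_mass_da = monomer_mass_da,
                 core_only = isTRUE(core_only)),
            class = "stoich_constants")
}

stoich_result <- function(input_kind, input_value, mass_da, exact) {
  structure(list(input_kind = input_kind,
                 input_value = input_value,
                 mass_da = mass_da,
                 monomer_count_exact = exact,
                 monomer_count = as.integer(round(exact))),
            class = "stoich_result")
}

#' @export
print.stoich_result <- function(x, ...) {
  cat(sprintf("%s = %g -> mass %s kDa, %.4g monomers (~%d-mer)\n",
              x$input_kind, x$input_value,
              format(signif(x$mass_da / 1000, 2)),
              x$monomer_count_exact, x$monomer_count))
  invisible(x)
}

#' Map volume to molecular mass
#'
#' `mass = volume x density_conversion` with the protein density
#' conversion of 825 Da per cubic nm (equivalently 0.825 Da per cubic
#' Angstrom): a 64,000 cubic-Angstrom map corresponds to 52.8 kDa.
#'
#' @param volume_a3 Map volume in cubic Angstrom (> 0).
#' @param constants [stoich_constants()]; `density_conversion` is in
#'   Da per cubic nm.
#' @return Mass in Da.
#' @export
volume_to_mass <- function(volume_a3, constants = stoich_constants()) {
  stopifnot(inherits(constants, "stoich_constants"), is.numeric(volume_a3))
  if (any(volume_a3 <= 0)) stop("volume must be positive")
  (volume_a3 / 1000) * constants$density_conversion
}

#' Molecular mass to monomer count
#'
#' Divides mass by the monomer mass; reports both the exact quotient and
#' the nearest-integer oligomer order (52.8 kDa / 4.514 kDa = 11.7, a
#' dodecamer).
#'
#' @param mass_da Mass in Da (> 0).
#' @param constants [stoich_constants()]; use `core_only = TRUE` there to
#'   count ordered-core monomers only.
#' @return A `stoich_result`.
#' @export
mass_to_monomers <- function(mass_da, constants = stoich_constants()) {
  stopifnot(inherits(constants, "stoich_constants"))
  if (!is.numeric(mass_da) || any(mass_da <= 0)) stop("mass must be positive")
  stoich_result("mass_da", mass_da, mass_da, mass_da / constants$monomer_mass_da)
}

#' Filament length to monomer count and mass
#'
#' Each monomer adds one 0.48-nm cross-beta strand to the filament, so
#' `monomers = length / strand_rise`; 48 nm corresponds to 100 monomers
#' (~450 kDa).
#'
#' @param length_nm Filament length, nm (> 0).
#' @param constants [stoich_constants()].
#' @return A `stoich_result` with mass `= exact count x monomer mass`.
#' @export
length_to_monomers <- function(length_nm, constants = stoich_constants()) {
  stopifnot(inherits(constants, "stoich_constants"))
  if (!is.numeric(length_nm) || any(length_nm <= 0)) stop("length must be positive")
  exact <- length_nm / constants$strand_rise_nm
  stoich_result("length_nm", length_nm, exact * constants$monomer_mass_da, exact)
}

#' Elongation rate to monomer addition rate
#'
#' `rate / strand_rise`: an end growing at 8.0 nm/min adds 16.67
#' monomers per minute.
#'
#' @param rate_nm_min Elongation rate, nm/min (>= 0).
#' @param constants [stoich_constants()].
#' @return Monomer addition rate, 1/min (float).
#' @export
rate_to_monomer_rate <- function(rate_nm_min, constants = stoich_constants()) {
  stopifnot(inherits(constants, "stoich_constants"), is.numeric(rate_nm_min))
  if (any(rate_nm_min < 0)) stop("rate must be non-negative")
  rate_nm_min / constants$strand_rise_nm
}
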