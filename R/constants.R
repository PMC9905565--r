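#' Metabolic-equation constants
#'
#' Parameters of the Boltzmann-Arrhenius individual metabolic rate model for
#' insects (springtails included),
#' \deqn{I = \exp(\ln i_0 + a \ln M - E / (k T))}
#' with \eqn{I} in J h\eqn{^{-1}} and \eqn{M} in mg fresh mass.
#'
#' @param ln_i0 natural-log normalization factor, J h^-1 scale (default
#'   21.972).
#' @param a allometric exponent, dimensionless (default 0.759).
#' @param E activation energy, eV (default 0.657).
#' @param k Boltzmann constant, eV K^-1 (8.617e-5).
#' @return named list with class \code{"MetabolicConstants"}.
#' @examples
#' metabolicConstants()
#' @seealso [individualMetabolicRate()]
#' @export
metabolicConstants <- function(ln_i0 = 21.972, a = 0.759, E = 0.657,
                               k = 8.617e-5) {
  stopIfNot(all(c(ln_i0, a, E, k) > 0), "metabolic constants must be positive")
  structure(list(ln_i0 = ln_i0, a = a, E = E, k = k),
            class = "MetabolicConstants")
}

#' Energy-to-carbon conversion constants
#'
#' Constants linking community metabolism (J per unit time) to carbon mass:
#' the energy density of fresh tissue, the water fraction of springtail
#' bodies, and the carbon fraction of dry mass.
#'
#' @param energy_density J per kg fresh mass (default 7e6).
#' @param water_fraction proportion of fresh mass that is water (default
#'   0.70).
#' @param carbon_fraction_of_dry carbon proportion of dry mass (default 0.45).
#' @return named list with class \code{"CarbonConstants"}.
#' @seealso [energyToCarbon()]
#' @export
carbonConstants <- function(energy_density = 7e6, water_fraction = 0.70,
                            carbon_fraction_of_dry = 0.45) {
  stopIfNot(energy_density > 0, "energy_density must be positive")
  stopIfNot(water_fraction > 0 && water_fraction < 1,
            "water_fraction must be in (0, 1)")
  stopIfNot(carbon_fraction_of_dry > 0 && carbon_fraction_of_dry < 1,
            "carbon_fraction_of_dry must be in (0, 1)")
  structure(list(energy_density = energy_density,
                 water_fraction = water_fraction,
                 carbon_fraction_of_dry = carbon_fraction_of_dry),
            class = "CarbonConstants")
}

# hours in an average month (365.25 * 24 / 12)
HOURS_PER_MONTH <- 730.5

# Earth mean radius in metres, for spherical pixel areas and great-circle
# distances.
EARTH_RADIUS_M <- 6371000
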