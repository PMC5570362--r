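# Physical and unit-conversion constants used across the package.

#' Unit constant of the ETR_RCII equation
#'
#' The electron transport rate per PSII reaction centre is the product of
#' irradiance (umol quanta m^-2 s^-1), the light-regulated functional
#' absorption cross-section sigma_PSII' (A^2 RCII^-1) and the fraction of
#' open centres Fq'/Fv'. Bringing those units onto mol e- mol RCII^-1 s^-1
#' requires Avogadro's number (quanta per mol, 6.022e23), umol -> mol (1e-6)
#' and A^2 -> m^2 (1e-20), whose product is 6.022e-3.
#'
#' @return The dimensionless unit-conversion constant, 6.022e-3.
#' @export
#' @examples
#' etr_unit_constant() # 0.006022
etr_unit_constant <- function() {
  avogadro <- 6.022e23   # quanta per mol
  umol_to_mol <- 1e-6
  A2_to_m2 <- 1e-20
  avogadro * umol_to_mol * A2_to_m2
}

# Molar masses for the C-assimilation unit conversion (g mol^-1).
CHLA_MOLAR_MASS <- 893.5
C_MOLAR_MASS <- 12

# Conventional isotope discrimination factor for 14C uptake.
C14_DISCRIMINATION <- 1.05

# Growth irradiance of the culture experiments (umol quanta m^-2 s^-1).
GROWTH_IRRADIANCE <- 155
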