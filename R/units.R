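# Physical constants. All package energies are expressed in kBT; temperature
# enters only through the mV <-> kBT and kcal/mol <-> kBT conversions.

#' @noRd
LN10 <- log(10)

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872041

# e^2/(4 pi eps0), kcal Angstrom / mol (vacuum Coulomb constant for unit charges)
COULOMB_KCAL_A <- 332.0637128

#' Thermal voltage kBT/e in millivolts
#'
#' @param temperature Temperature in Kelvin.
#' @return kBT/e in mV (25.85 mV at 300 K).
#' @export
kbt_mv <- function(temperature = 300) {
  kb <- 1.380649e-23   # J/K
  e  <- 1.602176634e-19 # C
  1000 * kb * temperature / e
}

#' Membrane potential in kBT units
#'
#' Converts a transmembrane electrical potential in mV to the energy (in kBT)
#' gained by one elementary charge crossing the full potential difference.
#'
#' @param delta_psi_mv Membrane potential in mV.
#' @param temperature Temperature in Kelvin.
#' @return Energy in kBT.
#' @export
psi_kbt <- function(delta_psi_mv, temperature = 300) {
  delta_psi_mv / kbt_mv(temperature)
}

#' Proton-motive-force driving energy per proton
#'
#' Total free energy released per proton moved from the proton-rich (IMS)
#' to the proton-poor (matrix) compartment:
#' \eqn{\Delta G = \ln(10)\,\Delta pH + e\Delta\Psi/k_BT} (in kBT), where
#' \eqn{\Delta pH = pH_{matrix} - pH_{IMS}}. One pH unit alone contributes
#' \eqn{\ln(10) \approx 2.3\,k_BT}.
#'
#' @param delta_ph pH difference, matrix minus IMS (dimensionless).
#' @param delta_psi_mv Membrane potential in mV (0 to ignore the electrical
#'   term).
#' @param temperature Temperature in Kelvin.
#' @return Driving energy in kBT.
#' @export
pmf_driving_energy <- function(delta_ph, delta_psi_mv = 0, temperature = 300) {
  LN10 * delta_ph + psi_kbt(delta_psi_mv, temperature)
}

# angle helpers: degrees everywhere at the interface, radians only for trig
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle to [0, 360)
wrap360 <- function(x) x %% 360

# wrap angle difference to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
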