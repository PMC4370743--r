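# Physical constants and unit conversions. All internal energies are in kBT
# at the working temperature; the reporting layer converts to kcal/mol.

# Coulomb constant e^2/(4 pi eps0), kcal*Angstrom/(mol*e^2)
COULOMB_KCAL <- 332.0637
# Boltzmann constant, kcal/(mol*K)
KB_KCAL <- 0.0019872041
# mol/L -> ions per cubic Angstrom
MOLAR_TO_A3 <- 6.02214076e-4

#' Convert energies between kBT and kcal/mol
#'
#' One kBT at 37 C is 0.61633 kcal/mol.
#'
#' @param x numeric energies.
#' @param temperature_celsius temperature in Celsius at which kBT is taken.
#' @return numeric of the same length as `x`.
#' @export
kbt_to_kcal <- function(x, temperature_celsius = 37) {
  x * KB_KCAL * (temperature_celsius + 273.15)
}

#' @rdname kbt_to_kcal
#' @export
kcal_to_kbt <- function(x, temperature_celsius = 37) {
  x / (KB_KCAL * (temperature_celsius + 273.15))
}

# e^2/(kB T) in Angstrom * kBT/e^2 -- the Bjerrum prefactor used to make the
# grid equations dimensionless (potential in kBT/e, length in Angstrom).
coulomb_kbt <- function(temperature_celsius) {
  COULOMB_KCAL / (KB_KCAL * (temperature_celsius + 273.15))
}

tbion_error <- function(msg, class, ...) {
  stop(structure(class = c(class, "tbion_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
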