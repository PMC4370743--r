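#' Temperature-dependent dielectric constant of water
#'
#' Empirical cubic polynomial in the Celsius temperature:
#' eps_w(T) = 87.740 - 0.4008 T + 9.398e-4 T^2 - 1.41e-6 T^3.
#' At 25 C this gives 78.3 (the familiar room-temperature value).
#'
#' @param temperature_celsius temperature in Celsius, in [0, 100].
#' @return the dimensionless dielectric constant.
#' @examples
#' dielectric_of_water(25)
#' @export
dielectric_of_water <- function(temperature_celsius) {
  if (!is.numeric(temperature_celsius) ||
      any(temperature_celsius < 0 | temperature_celsius > 100))
    tbion_error("temperature must be in [0, 100] Celsius", "tbion_bad_argument")
  t <- temperature_celsius
  87.740 - 0.4008 * t + 9.398e-4 * t^2 - 1.41e-6 * t^3
}

#' Solution condition: temperature and ionic composition
#'
#' Bundles the temperature with the bulk Na+ and Mg2+ concentrations. Cl- is
#' added implicitly to neutralize the bulk ([Cl-] = [Na+] + 2[Mg2+]). The
#' water dielectric constant is computed from the temperature via
#' [dielectric_of_water()] unless overridden; the RNA interior dielectric
#' defaults to 12.
#'
#' @param temperature_celsius temperature in Celsius (default 37).
#' @param na bulk Na+ concentration, mol/L.
#' @param mg bulk Mg2+ concentration, mol/L.
#' @param eps_in interior (RNA) dielectric constant, default 12.
#' @param eps_w water dielectric constant; `NULL` (default) computes it from
#'   the temperature.
#' @return an object of class `solution_condition`.
#' @examples
#' solution_condition(37, na = 0.1, mg = 0.01)
#' @export
solution_condition <- function(temperature_celsius = 37, na = 0.1, mg = 0,
                               eps_in = 12, eps_w = NULL) {
  if (na < 0 || mg < 0)
    tbion_error("ion concentrations must be non-negative", "tbion_bad_argument")
  if (is.null(eps_w)) eps_w <- dielectric_of_water(temperature_celsius)
  if (eps_in <= 1 || eps_w <= eps_in)
    tbion_error("need eps_in > 1 and eps_w > eps_in", "tbion_bad_argument")
  structure(list(
    temperature_celsius = temperature_celsius,
    t_kelvin = temperature_celsius + 273.15,
    c_na = na, c_mg = mg, c_cl = na + 2 * mg,
    eps_in = eps_in, eps_w = eps_w
  ), class = "solution_condition")
}

#' @export
print.solution_condition <- function(x, ...) {
  cat(sprintf("Solution: %.5g M Na+, %.5g M Mg2+ (Cl- %.5g M), T = %g C\n",
              x$c_na, x$c_mg, x$c_cl, x$temperature_celsius))
  cat(sprintf("  eps_in = %g, eps_w = %.3f\n", x$eps_in, x$eps_w))
  invisible(x)
}

# Mobile species table for the PB solver: valence, bulk number density
# (1/A^3), hydrated radius, and the exclusion distance from the molecular
# surface. Mg2+ centers are additionally excluded from the tightly bound
# layer (thickness t_shell beyond contact): ions there are treated
# discretely by the mode ensemble, so counting mean-field Mg2+ in the same
# shell would double count. Species at zero concentration are dropped.
condition_species <- function(cond, config) {
  ir <- config$ion_radius
  sp <- data.frame(
    name = c("Na", "Mg", "Cl"),
    z = c(1, 2, -1),
    c_molar = c(cond$c_na, cond$c_mg, cond$c_cl),
    radius = as.numeric(ir[c("Na", "Mg", "Cl")]),
    stringsAsFactors = FALSE
  )
  sp$excl <- sp$radius
  sp$excl[sp$name == "Mg"] <- sp$radius[sp$name == "Mg"] + config$t_shell
  sp <- sp[sp$c_molar > 0, , drop = FALSE]
  sp$c_a3 <- sp$c_molar * MOLAR_TO_A3
  sp
}

# Inverse Debye length, 1/Angstrom, from the full ionic strength.
debye_kappa <- function(cond, config) {
  sp <- condition_species(cond, config)
  if (!nrow(sp)) return(0)
  C <- coulomb_kbt(cond$temperature_celsius)
  sqrt(4 * pi * C * sum(sp$z^2 * sp$c_a3) / cond$eps_w)
}
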