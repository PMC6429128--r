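#' Physical constants (CODATA)
#'
#' Fixed CODATA values used throughout: Avogadro constant (1/mol),
#' Boltzmann constant (J/K), elementary charge (C) and vacuum permittivity
#' (F/m).
#'
#' @return A named list with `avogadro`, `boltzmann`, `elementary_charge`,
#'   `vacuum_permittivity`.
#' @export
physical_constants <- function() {
  list(avogadro = 6.02214076e23,
       boltzmann = 1.380649e-23,
       elementary_charge = 1.602176634e-19,
       vacuum_permittivity = 8.8541878128e-12)
}

#' Solvent / buffer conditions
#'
#' Container for the solution conditions every reduction depends on.
#' Hydrodynamic defaults are T = 293 K and eta = 1.002 mPa s (water at
#' 20 C); electrokinetic reductions conventionally use 298 K and
#' eps_r = 78.5, which must be set explicitly (see
#' [electro_conditions()]).
#'
#' @param temperature absolute temperature, K.
#' @param viscosity dynamic viscosity of the solvent, mPa s.
#' @param relative_permittivity relative dielectric constant (dimensionless).
#' @param ionic_strength ionic strength, mol/L.
#' @return A `hc_conditions` list.
#' @export
solvent_conditions <- function(temperature = 293, viscosity = 1.002,
                               relative_permittivity = 78.5,
                               ionic_strength = 0.15) {
  vals <- c(temperature = temperature, viscosity = viscosity,
            relative_permittivity = relative_permittivity,
            ionic_strength = ionic_strength)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all solvent condition fields must be finite and strictly positive")
  structure(list(temperature = temperature, viscosity = viscosity,
                 relative_permittivity = relative_permittivity,
                 ionic_strength = ionic_strength),
            class = "hc_conditions")
}

#' @rdname solvent_conditions
#' @details `electro_conditions()` is the electrokinetic convention:
#'   298 K, 0.89 mPa s, eps_r 78.5 and 0.17 M ionic strength (150 mM NaCl
#'   plus 20 mM Tris-HCl counted as fully dissociated at pH 7.5).
#' @export
electro_conditions <- function(temperature = 298, viscosity = 0.89,
                               relative_permittivity = 78.5,
                               ionic_strength = 0.17) {
  solvent_conditions(temperature, viscosity, relative_permittivity,
                     ionic_strength)
}

#' @export
print.hc_conditions <- function(x, ...) {
  cat(sprintf("<conditions> T = %g K, eta = %g mPa s, eps_r = %g, I = %g mol/L\n",
              x$temperature, x$viscosity, x$relative_permittivity,
              x$ionic_strength))
  invisible(x)
}

# viscosity in SI (Pa s)
eta_si <- function(conditions) conditions$viscosity * 1e-3
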