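#' Physical constants and unit conversions
#'
#' All energies are in kcal/mol, times in ps, distances in Angstrom.
#' `kB` is the Boltzmann constant in kcal mol^-1 K^-1; `water_viscosity`
#' the dynamic viscosity of water at 300 K in Pa s.
#'
#' @format A named list with elements `kB`, `kB_SI`, `water_viscosity`.
#' @export
mmsm_constants <- list(
  kB = 0.0019872041,        # kcal mol^-1 K^-1
  kB_SI = 1.380649e-23,     # J K^-1
  water_viscosity = 0.8937e-3  # Pa s at 300 K
)

#' Stokes-Einstein diffusion coefficient
#'
#' Translational diffusion coefficient of a sphere in water,
#' D = kB T / (6 pi eta R), converted to Angstrom^2/ps.
#'
#' @param temperature temperature in K.
#' @param radius Stokes radius in Angstrom.
#' @param viscosity dynamic viscosity in Pa s (default: water at 300 K).
#' @return diffusion coefficient in Angstrom^2/ps.
#' @export
stokes_einstein_diffusion <- function(temperature, radius,
                                      viscosity = mmsm_constants$water_viscosity) {
  stopifnot(temperature > 0, radius > 0, viscosity > 0)
  D_si <- mmsm_constants$kB_SI * temperature / (6 * pi * viscosity * radius * 1e-10)
  D_si * 1e8  # m^2/s -> A^2/ps  (1e20 A^2/m^2 / 1e12 ps/s)
}
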