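#' Physical constants and packaged defaults
#'
#' Returns the constants used throughout the package, all in SI units
#' except where noted. Any entry can be overridden by supplying it in the
#' `overrides` list; unit conversions live only at this boundary so the
#' math modules never see mixed units.
#'
#' @param overrides Named list of values replacing the packaged defaults.
#'
#' @return A list with elements:
#' \describe{
#'   \item{boltzmann_k}{Boltzmann constant, J/K.}
#'   \item{gamma_31p}{Gyromagnetic ratio of 31P, rad s^-1 T^-1.}
#'   \item{nu0_31p_mhz}{31P Larmor frequency at 11.7 T, MHz.}
#'   \item{water_viscosity_default}{Dynamic viscosity of D2O at 298 K, Pa s.}
#'   \item{temperature_default}{K.}
#' }
#' @examples
#' phos_constants()$gamma_31p
#' phos_constants(list(temperature_default = 300))$temperature_default
#' @export
phos_constants <- function(overrides = list()) {
  defaults <- list(
    boltzmann_k             = 1.380649e-23,
    gamma_31p               = 10.8394e7,
    nu0_31p_mhz             = 202.4,
    water_viscosity_default = 1.095e-3,
    temperature_default     = 298
  )
  stopifnot(is.list(overrides))
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0L) {
    stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- utils::modifyList(defaults, overrides)
  if (!all(vapply(out, function(x) is.numeric(x) && x > 0, logical(1)))) {
    stop("all physical constants must be strictly positive", call. = FALSE)
  }
  out
}

#' Convert a chemical-shift interval from ppm to angular frequency
#'
#' @param delta_ppm Shift interval in ppm.
#' @param nu0_mhz Larmor frequency in MHz.
#' @return Angular frequency in rad/s (ppm x MHz = Hz, times 2 pi).
#' @examples
#' ppm_to_rad_s(1, 100) # 2 * pi * 100
#' @export
ppm_to_rad_s <- function(delta_ppm, nu0_mhz) {
  2 * pi * delta_ppm * nu0_mhz
}

#' Larmor angular frequency from a frequency in MHz
#'
#' @param nu0_mhz Larmor frequency in MHz.
#' @return omega0 in rad/s.
#' @export
larmor_omega0 <- function(nu0_mhz) {
  stopifnot(is.numeric(nu0_mhz), nu0_mhz > 0)
  2 * pi * nu0_mhz * 1e6
}
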