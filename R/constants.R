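#' Physical constants used throughout the package
#'
#' Energies are handled in kcal/mol, distances in angstrom, time in
#' femtoseconds, masses in atomic mass units and temperatures in kelvin.
#' The gas constant is the CODATA-derived value in kcal/(mol K); the
#' Boltzmann and Planck constants are the 2019 exact SI values, and the
#' Coulomb prefactor follows the AMBER convention.
#'
#' @return A named list with components:
#'   \describe{
#'     \item{R}{gas constant, 1.9872041e-3 kcal/(mol K)}
#'     \item{kB}{Boltzmann constant, J/K}
#'     \item{h}{Planck constant, J s}
#'     \item{T_default}{default temperature, 298.15 K}
#'     \item{coulomb}{Coulomb prefactor, 332.0636 kcal A/(mol e^2)}
#'     \item{accel}{conversion from (kcal/mol/A)/amu to A/fs^2}
#'   }
#' @examples
#' thermo_constants()$R * 298.15   # RT at room temperature, kcal/mol
#' @export
thermo_constants <- function() {
  list(
    R         = 1.9872041e-3,
    kB        = 1.380649e-23,
    h         = 6.62607015e-34,
    T_default = 298.15,
    coulomb   = 332.0636,
    accel     = 4.184e-4
  )
}

.const <- thermo_constants()

#' Eyring frequency prefactor kB*T/h
#'
#' @param T temperature in K (default 298.15)
#' @return attempt frequency in 1/s; strictly increasing in \code{T}
#' @examples
#' eyring_prefactor()        # about 6.21e12 s^-1
#' @export
eyring_prefactor <- function(T = .const$T_default) {
  stopifnot(is.numeric(T), all(is.finite(T)))
  if (any(T <= 0)) stop("temperature must be positive")
  .const$kB * T / .const$h
}

# RT in kcal/mol
.RT <- function(T) .const$R * T

#' Format numbers as mantissa times power of ten
#'
#' Scientific notation with a fixed number of significant digits, in the
#' style used for tabulated rate constants and lifetimes
#' (e.g. \code{"2.56e-42"}).
#'
#' @param x numeric vector
#' @param digits significant digits (default 3)
#' @return character vector
#' @export
format_sci <- function(x, digits = 3) {
  formatC(x, format = "e", digits = digits - 1)
}
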