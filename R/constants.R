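#' Physical constants used throughout the package
#'
#' All energies in the package are carried in electron-volts, distances in
#' angstroms (nanometres for solution-scale pair statistics), temperatures in
#' kelvin and rates in inverse nanoseconds.  Every unit conversion flows
#' through this single table so that reported rate constants are reproducible
#' to the last digit.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{kB_eV}{Boltzmann constant, eV K^-1 (8.617333e-5)}
#'     \item{hbar_eVs}{Reduced Planck constant, eV s (6.582120e-16)}
#'     \item{coulomb_eVA}{Coulomb constant e^2/(4 pi eps0), eV Angstrom (14.3996)}
#'     \item{hartree_eV}{1 hartree in eV (27.2114)}
#'     \item{bohr_A}{1 bohr in Angstrom (0.529177)}
#'     \item{avogadro}{Avogadro constant, mol^-1}
#'   }
#' @examples
#' physical_constants()$kB_eV * 300  # thermal energy at 300 K in eV
#' @export
physical_constants <- function() {
  list(
    kB_eV       = 8.617333e-5,
    hbar_eVs    = 6.582120e-16,
    coulomb_eVA = 14.3996,
    hartree_eV  = 27.2114,
    bohr_A      = 0.529177,
    avogadro    = 6.02214076e23
  )
}

# internal shorthand: thermal energy in eV
.kT <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0)
    stop("'temperature' must be a single positive number (kelvin)", call. = FALSE)
  physical_constants()$kB_eV * temperature
}

.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
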