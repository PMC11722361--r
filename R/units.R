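#' Physical constants and unit conversions
#'
#' All internal computations use nm for length, kJ/mol for energy, ps for
#' time, K for temperature and amu for mass. PDB files and H-bond criteria
#' are expressed in Angstrom at the user boundary, and alchemical free
#' energies are conventionally reported in kcal/mol; these helpers do the
#' conversions in one place.
#'
#' @format `pam_constants` is a list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.0083144621 kJ/mol/K.}
#'   \item{R}{molar gas constant, 8.3144621 J/mol/K.}
#'   \item{hbar}{reduced Planck constant, kJ/mol * ps.}
#'   \item{f_coulomb}{Coulomb prefactor 1/(4 pi eps0), kJ mol^-1 nm e^-2.}
#'   \item{kcal}{kJ per kcal, 4.184.}
#' }
#' @export
pam_constants <- list(
  kB        = 0.0083144621,   # kJ/mol/K
  R         = 8.3144621,      # J/mol/K
  hbar      = 0.0635077993,   # kJ/mol * ps  (1.054571817e-34 J s * NA / 1000 * 1e12)
  f_coulomb = 138.935458,     # kJ mol^-1 nm e^-2
  kcal      = 4.184           # kJ per kcal
)

#' @rdname pam_constants
#' @param x numeric vector to convert.
#' @export
nm_to_ang <- function(x) x * 10

#' @rdname pam_constants
#' @export
ang_to_nm <- function(x) x / 10

#' @rdname pam_constants
#' @export
kj_to_kcal <- function(x) x / pam_constants$kcal

#' @rdname pam_constants
#' @export
kcal_to_kj <- function(x) x * pam_constants$kcal

#' Thermal energy kT
#'
#' @param temperature temperature in K.
#' @return kB*T in kJ/mol.
#' @export
kT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  pam_constants$kB * temperature
}
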