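#' Physical constants and unit conversions
#'
#' Internal units are kcal/mol (energy), Angstrom (length), ps (time),
#' g/mol (mass) and elementary charges. All conversions between these and
#' derived quantities go through the single set of named constants below.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal mol^-1 K^-1.}
#'   \item{coulomb}{Coulomb prefactor, kcal Angstrom mol^-1 e^-2, so that the
#'     energy of two unit charges 1 Angstrom apart is `coulomb` kcal/mol.}
#'   \item{mv2_to_kcal}{Converts g mol^-1 (Angstrom/ps)^2 to kcal/mol.}
#'   \item{acc}{Converts (kcal mol^-1 Angstrom^-1)/(g mol^-1) to Angstrom ps^-2.}
#'   \item{press_atm}{Converts kcal mol^-1 Angstrom^-3 to atm.}
#'   \item{avogadro_dens}{N_A * 1e-24: divides g/mol by (this * V[A^3]) to get g/cm^3.}
#' }
#' @export
cg_constants <- list(
  kB            = 0.001987204259,
  coulomb       = 332.063713,
  mv2_to_kcal   = 10 / 4184,            # 2.390057e-3
  acc           = 4184 / 10,            # 418.4
  press_atm     = 4184 / 6.02214076e-1 / 101325 * 1e6,  # 68568.5 atm per kcal/mol/A^3
  avogadro_dens = 0.602214076
)

#' Kinetic energy of a set of velocities
#'
#' @param vel N x 3 matrix of velocities, Angstrom/ps.
#' @param mass length-N vector of masses, g/mol.
#' @return Kinetic energy in kcal/mol.
#' @export
kinetic_energy <- function(vel, mass) {
  0.5 * sum(mass * rowSums(vel^2)) * cg_constants$mv2_to_kcal
}

#' Instantaneous kinetic temperature
#'
#' Uses the constrained degree-of-freedom count: `ndof` must already account
#' for removed centre-of-mass motion and holonomic constraints.
#'
#' @param vel N x 3 velocity matrix, Angstrom/ps.
#' @param mass masses, g/mol.
#' @param ndof number of kinetic degrees of freedom.
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(vel, mass, ndof) {
  2 * kinetic_energy(vel, mass) / (ndof * cg_constants$kB)
}

#' Degrees of freedom of a topology
#'
#' 3N minus 3 (centre-of-mass momentum is zeroed and conserved) minus 3 per
#' rigid water (three distance constraints each).
#'
#' @param topology a `cg_topology`.
#' @return Integer degree-of-freedom count.
#' @export
n_dof <- function(topology) {
  n <- nrow(topology$pos)
  nw <- if (is.null(topology$waters)) 0L else nrow(topology$waters)
  3L * n - 3L - 3L * nw
}
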