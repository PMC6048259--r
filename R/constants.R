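#' Physical constants used throughout the package
#'
#' All energies are in kcal/mol, distances in Angstrom, masses in amu,
#' times in fs, temperatures in Kelvin.
#'
#' @format `kB_KCAL` is the Boltzmann constant in kcal/(mol K);
#'   `COULOMB_KCAL` is the electrostatic conversion factor such that
#'   `COULOMB_KCAL * q1 * q2 / r` is in kcal/mol for charges in units of the
#'   elementary charge and `r` in Angstrom; `ACC_CONV` converts a force in
#'   kcal/mol/Angstrom acting on a mass in amu into an acceleration in
#'   Angstrom/fs^2.
#' @name constants
NULL

#' @rdname constants
#' @export
kB_KCAL <- 1.9872e-3

#' @rdname constants
#' @export
COULOMB_KCAL <- 332.0637

# 1 kcal/mol/(A amu) = 4.184e-4 A/fs^2
ACC_CONV <- 4.184e-4
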