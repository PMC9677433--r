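## Physical constants shared across modules.  The Coulomb constant is fixed at the
## value used by classic liquid-state simulation codes so that golden energies
## reproduce; do not silently "improve" it.

#' Physical constants used throughout the package
#'
#' @description
#' * `kCoulomb`: Coulomb constant, 332.06 kcal Angstrom / (mol e^2).
#' * `kBoltzmann`: Boltzmann constant, kcal / (mol K).
#' * `atmPerKcalA3`: 1 atm expressed in kcal / (mol Angstrom^3), used in the
#'   NPT acceptance weight.
#' * `kcalPerCm3Atm`: 1 cm^3 atm in kcal (0.024217 cal exactly), used to turn
#'   excess volumes into free-energy slopes.
#' @name ionhyd-constants
#' @keywords internal
NULL

kCoulomb <- 332.06
kBoltzmann <- 1.9872041e-3
atmPerKcalA3 <- 1.4584e-5
kcalPerCm3Atm <- 0.024217e-3
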