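## Molecular models: rigid four-site water, monoatomic LJ/Coulomb ions, sharp
## molecule-based truncation under cubic periodic boundary conditions.
##
## Conventions used throughout:
##  - the ion sits at the origin of the box and never moves; water oxygens are
##    kept wrapped into [-L/2, L/2)^3;
##  - truncation is all-or-nothing per molecule pair, keyed to the O-O
##    minimum-image distance (water-water) and the ion-O distance (ion-water);
##  - LJ acts only between oxygens (and ion-O), Coulomb between the charge
##    sites (H, H, M) and the ion charge;
##  - combining rules are geometric mean for both sigma and epsilon;
##  - coupling scales the ion parameters linearly: sigma(lambda) = lambda*sigma,
##    eps(lambda) = lambda*eps, q(lambda) = lambda*q, so the Coulomb energy is
##    exactly linear in lambda_q and the LJ term vanishes at lambda_LJ = 0.

#' Load the packaged force field (water model + ion parameters)
#'
#' Reads the parameter file shipped under `extdata` (or a user file of the same
#' JSON layout).  The water model is a rigid four-site model: LJ on O only, a
#' negative charge on the M site displaced from O along the HOH bisector, and
#' positive charges on the hydrogens.
#'
#' @param file Path to a JSON parameter file; default is the packaged set.
#' @return A list with elements `water` (class `waterModel`) and `ions`
#'   (named list of class-`ionSpec` entries).
#' @export
loadForcefield <- function(file = system.file("extdata", "forcefield.json",
                                              package = "ionhyd")) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  water <- do.call(waterModel, raw$water[names(raw$water) != "comment"])
  ions <- lapply(names(raw$ions), function(nm) {
    p <- raw$ions[[nm]]
    ionSpec(nm, charge = p$charge, sigma = p$sigma, eps = p$eps)
  })
  names(ions) <- names(raw$ions)
  list(water = water, ions = ions)
}

#' Rigid four-site water model
#'
#' @param rOH O-H bond length (Angstrom).
#' @param thetaHOH H-O-H angle (degrees).
#' @param rOM O-M distance along the HOH bisector (Angstrom).
#' @param qH,qM Site charges (e); the molecule must be neutral (qM = -2 qH).
#' @param sigmaO,epsO LJ parameters on the oxygen (Angstrom, kcal/mol).
#' @param numberDensity1atm Bulk number density at 1 atm (Angstrom^-3), used by
#'   the box generator and the density-scaled correction.
#' @param name Model label.
#' @return Object of class `waterModel`.  `$siteOffsets` is a 4 x 3 matrix of
#'   molecular-frame site positions (rows O, H1, H2, M; bisector along +z),
#'   `$siteCharges` the corresponding charges.
#' @export
waterModel <- function(rOH = 0.9572, thetaHOH = 104.52, rOM = 0.15,
                       qH = 0.52, qM = -1.04, sigmaO = 3.15365, epsO = 0.155,
                       numberDensity1atm = 0.03333, name = "TIP4P") {
  stopifnot(rOH > 0, rOM >= 0, sigmaO > 0, epsO >= 0)
  if (abs(qM + 2 * qH) > 1e-12)
    stop("water molecule must be neutral: qM = -2 qH")
  half <- thetaHOH / 2 * pi / 180
  offsets <- rbind(
    O  = c(0, 0, 0),
    H1 = c( sin(half) * rOH, 0, cos(half) * rOH),
    H2 = c(-sin(half) * rOH, 0, cos(half) * rOH),
    M  = c(0, 0, rOM))
  structure(list(name = name, rOH = rOH, thetaHOH = thetaHOH, rOM = rOM,
                 qH = qH, qM = qM, sigmaO = sigmaO, epsO = epsO,
                 numberDensity1atm = numberDensity1atm,
                 siteOffsets = offsets,
                 siteCharges = c(0, qH, qH, qM)),
            class = "waterModel")
}

#' Monoatomic ion specification
#'
#' @param name Ion label, e.g. `"K+"`.
#' @param charge Ion charge in e; must be +1 or -1 for the ions in scope.
#' @param sigma,eps LJ parameters (Angstrom, kcal/mol), combined geometrically
#'   with the water oxygen parameters.
#' @return Object of class `ionSpec`.
#' @export
ionSpec <- function(name, charge, sigma, eps) {
  stopifnot(abs(charge) == 1, sigma > 0, eps > 0)
  structure(list(name = name, charge = charge, sigma = sigma, eps = eps),
            class = "ionSpec")
}

#' Sharp molecule-based cutoff scheme
#'
#' @param rIW Ion-water cutoff on the ion-O distance (Angstrom).
#' @param rWW Water-water cutoff on the O-O minimum-image distance (Angstrom).
#' @return Object of class `cutoffScheme`.
#' @export
cutoffScheme <- function(rIW = 11.5, rWW = 11.5) {
  stopifnot(rIW > 0, rWW > 0)
  structure(list(rIW = rIW, rWW = rWW), class = "cutoffScheme")
}

#' Coupling state of the ion-water interaction
#'
#' `(1, 1)` is the fully coupled ion, `(1, 0)` the uncharged LJ solute and
#' `(0, 0)` the fully decoupled solute.
#'
#' @param lambdaLJ,lambdaQ Coupling parameters in `[0, 1]` scaling the ion LJ
#'   parameters and the ion charge linearly.
#' @return Object of class `couplingState`.
#' @export
couplingState <- function(lambdaLJ = 1, lambdaQ = 1) {
  if (lambdaLJ < 0 || lambdaQ < 0) stop("negative coupling parameter")
  stopifnot(lambdaLJ <= 1, lambdaQ <= 1)
  structure(list(lambdaLJ = lambdaLJ, lambdaQ = lambdaQ),
            class = "couplingState")
}

#' Simulation configuration: one fixed ion plus N rigid waters in a cubic box
#'
#' The ion is pinned at the origin.  Each water is a rigid body described by
#' its oxygen position and a unit quaternion; all site coordinates derive from
#' these plus the water model geometry.
#'
#' @param L Cubic box edge (Angstrom).
#' @param positions N x 3 matrix of oxygen positions (Angstrom).
#' @param quaternions N x 4 matrix of unit quaternions (w, x, y, z).
#' @param ion Optional `ionSpec` carried along for bookkeeping.
#' @return Object of class `configuration`.
#' @export
newConfiguration <- function(L, positions, quaternions, ion = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  quaternions <- matrix(as.numeric(quaternions), ncol = 4)
  stopifnot(L > 0, nrow(positions) == nrow(quaternions))
  nrm <- sqrt(rowSums(quaternions^2))
  if (nrow(quaternions) > 0 && any(abs(nrm - 1) > 1e-8))
    quaternions <- quaternions / nrm
  positions <- wrapCoords(positions, L)
  structure(list(L = L, positions = positions, quaternions = quaternions,
                 ion = ion),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d waters in a cubic box, L = %.4f A%s\n",
              nWaters(x), x$L,
              if (!is.null(x$ion)) paste0(", ion ", x$ion$name) else ""))
  invisible(x)
}

#' Number of water molecules in a configuration
#' @param config A `configuration`.
#' @export
nWaters <- function(config) nrow(config$positions)

#' Wrap coordinates into the primary cell [-L/2, L/2)
#' @param x Matrix or vector of coordinates.
#' @param L Box edge.
#' @keywords internal
wrapCoords <- function(x, L) x - L * round(x / L)

#' Rotate the molecular-frame site offsets by a quaternion
#'
#' @param quaternion Unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @keywords internal
quatToMatrix <- function(quaternion) {
  w <- quaternion[1]; x <- quaternion[2]; y <- quaternion[3]; z <- quaternion[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Global site coordinates of one water molecule
#'
#' @param position Oxygen position (length-3).
#' @param quaternion Unit quaternion.
#' @param model A `waterModel`.
#' @return 4 x 3 matrix of site coordinates (O, H1, H2, M).
#' @export
waterSites <- function(position, quaternion, model) {
  R <- quatToMatrix(quaternion)
  sweep(model$siteOffsets %*% t(R), 2, position, `+`)
}

.ffPack <- function(model) {
  ## flat parameter vector consumed by the C++ kernels
  c(model$sigmaO, model$epsO, as.vector(t(model$siteOffsets)),
    model$siteCharges)
}

#' Water-water potential energy of a configuration
#'
#' Sums, over all water pairs whose minimum-image O-O distance is below the
#' water-water cutoff, the O-O LJ term plus the Coulomb interaction over all
#' charge-site pairs.  The image shift of a pair is decided once per molecule
#' pair from the oxygens (molecule-based truncation): a pair beyond the cutoff
#' contributes exactly zero.
#'
#' @param config A `configuration`.
#' @param model A `waterModel`.
#' @param cutoffs A `cutoffScheme`; `rWW` must not exceed `L/2`.
#' @return Energy in kcal/mol.
#' @export
waterWaterEnergy <- function(config, model, cutoffs) {
  checkCutoffs(cutoffs, config$L)
  cppWaterWaterEnergy(config$positions, config$quaternions, config$L,
                      .ffPack(model), cutoffs$rWW)
}

#' Ion-water potential energy of a configuration
#'
#' Sums, over waters whose minimum-image ion-O distance is below the ion-water
#' cutoff, the coupling-scaled ion-O LJ term plus the Coulomb interaction of
#' the scaled ion charge with the three water charge sites.
#'
#' @param config A `configuration`.
#' @param ion An `ionSpec`.
#' @param coupling A `couplingState`.
#' @param model A `waterModel`.
#' @param cutoffs A `cutoffScheme`; `rIW` must not exceed `L/2`.
#' @return Energy in kcal/mol.
#' @export
ionWaterEnergy <- function(config, ion, coupling, model, cutoffs) {
  checkCutoffs(cutoffs, config$L)
  cppIonWaterEnergy(config$positions, config$quaternions, config$L,
                    .ffPack(model), cutoffs$rIW,
                    ion$charge, ion$sigma, ion$eps,
                    coupling$lambdaLJ, coupling$lambdaQ)
}

#' Total potential energy (water-water plus ion-water)
#'
#' @inheritParams ionWaterEnergy
#' @param cutoffs A `cutoffScheme`.
#' @return Energy in kcal/mol.
#' @export
totalEnergy <- function(config, ion, coupling, model, cutoffs) {
  waterWaterEnergy(config, model, cutoffs) +
    ionWaterEnergy(config, ion, coupling, model, cutoffs)
}

checkCutoffs <- function(cutoffs, L) {
  if (cutoffs$rWW > L / 2 || cutoffs$rIW > L / 2)
    stop(sprintf(
      "cutoff exceeds L/2 = %.3f A: minimum-image convention violated", L / 2))
  invisible(TRUE)
}
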