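## Continuum-electrostatics corrections for molecular potential truncation.
##
## The charging free energy of a point charge in a spherical cavity is
## computed two ways: in closed form (Born) and numerically via apparent
## surface charges on a tessellated cavity (a boundary-element Poisson
## solver).  The numerical route exists so that a cutoff can be introduced in
## the surface-charge interaction matrix, mirroring the water-water cutoff of
## the simulations; the difference between the uncut and cut charging
## energies is the water-water truncation correction C_WW.

#' Born charging free energy of a point charge in a spherical cavity
#'
#' `dG = -(kC q^2 / 2R)(1 - 1/epsR)` with
#' `kC = 332.06 kcal Angstrom / (mol e^2)`.
#'
#' @param q Charge (e).
#' @param R Cavity radius (Angstrom).
#' @param epsR Relative permittivity of the medium (>= 1).
#' @return Free energy (kcal/mol).
#' @export
bornEnergy <- function(q, R, epsR) {
  stopifnot(R > 0)
  if (epsR < 1) stop("relative permittivity must be >= 1")
  -(kCoulomb * q^2 / (2 * R)) * (1 - 1 / epsR)
}

#' Long-range (beyond-cutoff) Born correction C_LR
#'
#' The Born energy of the dielectric beyond the cavity radius
#' `R_LR = R_IW + delta`, where `delta` accounts for the water molecule size
#' (the ion-water cutoff is keyed to the ion-O distance).  The default
#' `delta = 1.7` gives `R_LR = 13.2` at the production cutoff of 11.5.
#'
#' @param q Ion charge (e).
#' @param rIW Ion-water cutoff (Angstrom).
#' @param delta Water-size increment (Angstrom).
#' @param epsR Relative permittivity.
#' @return Correction (kcal/mol), negative for a dielectric.
#' @export
cLR <- function(q, rIW, delta = 1.7, epsR) bornEnergy(q, rIW + delta, epsR)

#' Quasi-uniform spherical tessellation (Fibonacci spiral)
#'
#' Deterministic point set with equal per-point areas `4 pi R^2 / n`.
#'
#' @param n Number of surface points.
#' @param R Sphere radius (Angstrom).
#' @return Object of class `sphericalCavity` with `points` (n x 3), `areas`
#'   and `R`.
#' @export
tessellateSphere <- function(n, R) {
  stopifnot(n >= 4, R > 0)
  i <- seq_len(n) - 1
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i + 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(ga * i), rho * sin(ga * i), z) * R
  structure(list(R = R, n = n, points = pts,
                 areas = rep(4 * pi * R^2 / n, n)),
            class = "sphericalCavity")
}

#' @export
print.sphericalCavity <- function(x, ...) {
  cat(sprintf("<sphericalCavity> R = %.2f A, %d surface points\n", x$R, x$n))
  invisible(x)
}

#' Build the surface-charge interaction matrix T
#'
#' Normal-field apparent-surface-charge discretisation: the polarization
#' charge density satisfies `sigma = -f E_in . n` with
#' `f = (epsR - 1) / (4 pi epsR)`, where `E_in` is the total field just
#' inside the surface (central charge + surface charges + the local sheet
#' jump).  Collocation over the tessellation gives the linear system
#' `T q_surf = -f E_n` with off-diagonal entries
#' `T_kj = f (r_k - r_j) . n_k / |r_k - r_j|^3` and a diagonal set by the
#' self-field closure:
#'
#' * `"local"` (default): flat-sheet self-field `-2 pi sigma_k`.  This is the
#'   classical discretisation; published truncation corrections at n = 1000
#'   are defined under it.
#' * `"cap"`: exact self-field of a spherical-cap element,
#'   `-2 pi sigma_k (1 - sin(alpha_k/2))` with cap half-angle `alpha_k` from
#'   the element area.  Converges to the Born value much faster.
#'
#' An optional cutoff zeroes the off-diagonal entries of pairs farther apart
#' than `cutoff` (symmetric mask, diagonal untouched), mirroring
#' molecule-pair truncation.
#'
#' @param cavity A `sphericalCavity`.
#' @param epsR Relative permittivity.
#' @param cutoff Inter-point cutoff (Angstrom) or `NULL` for none.
#' @param closure Diagonal self-field closure, `"local"` or `"cap"`.
#' @return Object of class `interactionMatrix`.
#' @export
buildT <- function(cavity, epsR, cutoff = NULL, closure = c("local", "cap")) {
  closure <- match.arg(closure)
  if (epsR < 1) stop("relative permittivity must be >= 1")
  if (!is.null(cutoff) && cutoff <= 0) stop("cutoff must be positive")
  pts <- cavity$points
  n <- cavity$n
  f <- (epsR - 1) / (4 * pi * epsR)
  nrm <- pts / cavity$R
  dx <- outer(pts[, 1], pts[, 1], `-`)
  dy <- outer(pts[, 2], pts[, 2], `-`)
  dz <- outer(pts[, 3], pts[, 3], `-`)
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  diag(dist) <- 1
  ## g_kj = (r_k - r_j) . n_k / |r_k - r_j|^3  (field at k from unit charge at j)
  g <- (dx * nrm[, 1] + dy * nrm[, 2] + dz * nrm[, 3]) / dist^3
  diag(g) <- 0
  Tm <- f * g
  selfField <- if (closure == "local") {
    rep(-2 * pi, n)
  } else {
    alpha <- acos(pmax(-1, 1 - cavity$areas / (2 * pi * cavity$R^2)))
    -2 * pi * (1 - sin(alpha / 2))
  }
  diag(Tm) <- (1 + f * selfField) / cavity$areas
  mask <- NULL
  if (!is.null(cutoff)) {
    mask <- dist > cutoff
    diag(mask) <- FALSE
    Tm[mask] <- 0
  }
  structure(list(T = Tm, cavity = cavity, epsR = epsR, cutoff = cutoff,
                 closure = closure, f = f, mask = mask),
            class = "interactionMatrix")
}

#' Solve for the apparent surface charges induced by a central charge
#'
#' Solves `T q_surf = -f E_n` for a point charge `q` at the cavity center
#' (`E_n = q / R^2` on the surface).  Without a cutoff the total surface
#' charge approaches the Gauss-law value `-q (1 - 1/epsR)` as the
#' tessellation refines.
#'
#' @param Tmat An `interactionMatrix`.
#' @param q Central charge (e).
#' @return Object of class `polarizationCharges` with the per-point charges
#'   and the cavity.
#' @export
solveCharges <- function(Tmat, q) {
  n <- Tmat$cavity$n
  if (q == 0) {
    qs <- rep(0, n)
  } else {
    rhs <- rep(-Tmat$f * q / Tmat$cavity$R^2, n)
    qs <- solve(Tmat$T, rhs)
    res <- sqrt(sum((Tmat$T %*% qs - rhs)^2)) / sqrt(sum(rhs^2))
    if (res > 1e-10)
      stop(sprintf("surface-charge solve residual %.2e above tolerance", res))
  }
  structure(list(charges = qs, cavity = Tmat$cavity, epsR = Tmat$epsR,
                 cutoff = Tmat$cutoff, q = q),
            class = "polarizationCharges")
}

#' Charging free energy from the polarization charges
#'
#' Half the Coulomb interaction between the surface charges and the central
#' charge: `dG_q = (1/2) sum_k kC q q_k / |r_k|`.
#'
#' @param charges A `polarizationCharges`.
#' @param q Central charge (e); defaults to the charge used in the solve.
#' @return Free energy (kcal/mol).
#' @export
dgQ <- function(charges, q = charges$q) {
  r <- sqrt(rowSums(charges$cavity$points^2))
  0.5 * kCoulomb * q * sum(charges$charges / r)
}

#' Water-water truncation correction C_WW
#'
#' `C_WW = dG_q(no cutoff) - dG_q(cutoff in T)` for a unit charge in a cavity
#' of radius `rLR`.  The cutoff makes the charging free energy more negative,
#' so the correction is positive.
#'
#' @param rLR Cavity radius (Angstrom).
#' @param epsR Relative permittivity.
#' @param waterCutoff Cutoff applied to the T matrix (Angstrom).
#' @param n Number of surface points.
#' @param q Central charge (e).
#' @param closure Diagonal closure, see [buildT()].
#' @return Correction (kcal/mol).
#' @export
cWW <- function(rLR, epsR, waterCutoff, n = 1000, q = 1,
                closure = c("local", "cap")) {
  closure <- match.arg(closure)
  cav <- tessellateSphere(n, rLR)
  full <- dgQ(solveCharges(buildT(cav, epsR, NULL, closure), q))
  cut <- dgQ(solveCharges(buildT(cav, epsR, waterCutoff, closure), q))
  full - cut
}

#' Discrete-charging form of C_WW with windowed partial sums
#'
#' The simulations charge the ion in finite increments `dq` over double-wide
#' windows rather than reversibly.  The matching correction is the windowed
#' sum of the per-increment continuum free-energy differences; partial sums
#' give the correction at intermediate coupled charge.  Since the continuum
#' charging energy is a state function scaling as the square of the charge,
#' the full sum telescopes to the continuous form.
#'
#' @param q Total ion charge (e).
#' @param dq Charge increment per half-window (e).
#' @param rLR,epsR,waterCutoff,n,closure As in [cWW()].
#' @return List with `total` and a data frame `partial` of the correction at
#'   each intermediate charge.
#' @export
cWWDiscrete <- function(q = 1, dq = 0.05, rLR, epsR, waterCutoff, n = 1000,
                        closure = c("local", "cap")) {
  closure <- match.arg(closure)
  if (q == 0)
    return(list(total = 0,
                partial = data.frame(charge = numeric(0),
                                     correction = numeric(0))))
  cav <- tessellateSphere(n, rLR)
  Tfull <- buildT(cav, epsR, NULL, closure)
  Tcut <- buildT(cav, epsR, waterCutoff, closure)
  ## unit-charge energies; charge Q scales both as Q^2
  eFull <- dgQ(solveCharges(Tfull, 1))
  eCut <- dgQ(solveCharges(Tcut, 1))
  steps <- seq(0, abs(q) / dq) * dq * sign(q)
  corr <- (eFull - eCut) * steps^2
  inc <- diff(corr)
  list(total = sum(inc),
       partial = data.frame(charge = steps[-1], correction = cumsum(inc)))
}

#' Density-scaled boundary-artifact correction C_BA
#'
#' Proportional to the water number density with the per-ion constant fixed
#' by the 1-atm boundary condition `C_BA(1 atm) = -deltaDg3(1 atm)`, so the
#' corrected 1-atm chemical potential matches the experimental reference.
#'
#' @param deltaDg3At1atm Residual discrepancy at 1 atm after the C_LR + C_WW
#'   corrections (kcal/mol).
#' @param rhoRatio Water number density at the target pressure relative to
#'   1 atm.
#' @return Correction (kcal/mol).
#' @export
cBA <- function(deltaDg3At1atm, rhoRatio) -deltaDg3At1atm * rhoRatio

#' Assemble the correction ledger for one ion at one state point
#'
#' `C1 = C_LR + C_WW`, `C2 = C1 + C_BA`, `C3 = C1 - Aq` (the identities hold
#' exactly by construction).
#'
#' @param cLR,cWW,cBA Corrections (kcal/mol); `cBA` may be `NA`.
#' @param Aq Static-potential interaction energy `A q` (kcal/mol); may be
#'   `NA`.
#' @param params Optional list of the parameters used (cutoffs, `rLR`,
#'   `epsR`, `n`), carried for provenance.
#' @return Object of class `correctionLedger`.
#' @export
correctionLedger <- function(cLR, cWW, cBA = NA_real_, Aq = NA_real_,
                             params = list()) {
  c1 <- cLR + cWW
  structure(list(cLR = cLR, cWW = cWW, cBA = cBA, Aq = Aq,
                 C1 = c1, C2 = c1 + cBA, C3 = c1 - Aq, params = params),
            class = "correctionLedger")
}

#' @export
print.correctionLedger <- function(x, ...) {
  cat(sprintf(paste0("<correctionLedger> C_LR = %.2f, C_WW = %.2f, ",
                     "C_BA = %.2f, Aq = %.2f; C1 = %.2f, C2 = %.2f, ",
                     "C3 = %.2f kcal/mol\n"),
              x$cLR, x$cWW, x$cBA, x$Aq, x$C1, x$C2, x$C3))
  invisible(x)
}
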