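## Analysis layer: charge-scaling fits, discrepancy ledgers against
## experimental hydration free energies, ion differences, electrolyte sums,
## pressure profiles and excess-volume reference lines.

#' Charging curve: leg free energy versus coupled charge
#'
#' @param lambdaQ Coupled-charge values `lambda q` (e), strictly increasing.
#' @param dg Free energies `dG(LJ -> LJ + lambda q)` (kcal/mol);
#'   `dG(0) = 0` by construction and need not be included.
#' @param se Optional uncertainties (kcal/mol).
#' @param ion,P Bookkeeping labels.
#' @return Object of class `chargingCurve`.
#' @export
chargingCurve <- function(lambdaQ, dg, se = NULL, ion = NA_character_,
                          P = NA_real_) {
  stopifnot(length(lambdaQ) == length(dg), !is.unsorted(lambdaQ,
                                                        strictly = TRUE))
  if (!is.null(se)) stopifnot(length(se) == length(dg), all(se >= 0))
  structure(list(lambdaQ = lambdaQ, dg = dg, se = se, ion = ion, P = P),
            class = "chargingCurve")
}

#' Quadratic (zero-intercept) fit of a charging curve
#'
#' Weighted least squares of `dG = A (lambda q) + B (lambda q)^2` over the
#' points inside the interval.  The linear coefficient `A` is the static
#' electrostatic potential at the solute site (kcal/(mol e)); the quadratic
#' coefficient `B` is the Born-like response.  The intercept is fixed at 0:
#' the charging leg starts from the uncharged LJ solute.
#'
#' @param curve A `chargingCurve`.
#' @param interval Fit interval `[lo, hi]` in the coupled charge.
#' @return Object of class `quadraticFit` with `A`, `B`, their covariance,
#'   residuals and the interval.
#' @export
fitChargingCurve <- function(curve, interval = c(0, 1)) {
  sel <- curve$lambdaQ >= interval[1] - 1e-12 &
    curve$lambdaQ <= interval[2] + 1e-12
  x <- curve$lambdaQ[sel]
  y <- curve$dg[sel]
  if (length(x) < 3) stop("need at least 3 points inside the fit interval")
  w <- if (!is.null(curve$se)) 1 / curve$se[sel]^2 else rep(1, length(x))
  fit <- stats::lm(y ~ 0 + x + I(x^2), weights = w)
  co <- stats::coef(fit)
  if (anyNA(co)) stop("singular design in charging-curve fit")
  ## vcov warns on an exactly-interpolating fit; the covariance is then
  ## meaningless anyway and reported as-is
  covm <- suppressWarnings(stats::vcov(fit))
  structure(list(A = unname(co[1]), B = unname(co[2]),
                 cov = covm,
                 residuals = stats::residuals(fit),
                 interval = interval, n = length(x), fit = fit),
            class = "quadraticFit")
}

#' @export
print.quadraticFit <- function(x, ...) {
  cat(sprintf(paste0("<quadraticFit> dG = A(lq) + B(lq)^2 over [%.2f, %.2f]",
                     " (%d pts): A = %.3f kcal/(mol e), B = %.3f",
                     " kcal/(mol e^2)\n"),
              x$interval[1], x$interval[2], x$n, x$A, x$B))
  invisible(x)
}

#' Load the packaged reference constants
#'
#' Experimental hydration free energies (conventional absolute scale), the
#' air/water interface potential of the water model, per-ion static
#' potentials at 1 atm, and the pressure tables of the dielectric constant
#' and relative water density.  These are configuration data, never computed.
#'
#' @param file Optional path to a JSON file with the same layout.
#' @return List of reference constants.
#' @export
referenceConstants <- function(file = system.file(
  "extdata", "reference_constants.json", package = "ionhyd")) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Load the packaged cluster-scale FEP reference table
#'
#' Per-(pressure, ion) leg free energies and their sum (the uncorrected
#' chemical potential) with statistical uncertainties, from production-scale
#' runs far beyond desk reproduction.  Inputs to the analysis layer.
#'
#' @param file Optional path to a TSV with the same columns.
#' @return Data frame with columns `P`, `ion`, `dgLJ`, `dgLJse`, `dgQ`,
#'   `dgQse`, `mu`, `muse`.
#' @export
fepReferenceTable <- function(file = system.file(
  "extdata", "fep_reference.tsv", package = "ionhyd")) {
  utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Discrepancy ledger against experimental hydration free energies
#'
#' For each ion at 1 atm: `dDG1 = mu*_FEP - dGhyd_exp`, `dDG2 = dDG1 + C_LR`,
#' `dDG3 = dDG2 + C_WW`, plus the static-potential and interface-potential
#' columns `dDG3 - Aq` and `dDG3 - Phi q` using the signed ion charge.
#' Values are computed unrounded; the `printed` companion rounds to one
#' decimal after the arithmetic.
#'
#' @param mu Named vector of uncorrected chemical potentials (kcal/mol).
#' @param reference Reference constants list (see [referenceConstants()]);
#'   uses `dGhydExp`, `phi` and (unless `Aq` is given) `A1atm`.
#' @param corr A `correctionLedger` (the corrections are ion-independent at
#'   fixed geometry apart from `Aq`).
#' @param charges Named vector of signed ion charges (e).
#' @param Aq Optional named vector of `A q` values (kcal/mol); defaults to
#'   `reference$A1atm * charges`.
#' @return List with data frames `ledger` (unrounded) and `printed` (rounded
#'   to one decimal).
#' @export
discrepancyLedger <- function(mu, reference, corr, charges, Aq = NULL) {
  ions <- names(mu)
  stopifnot(!is.null(ions), all(ions %in% names(reference$dGhydExp)),
            all(ions %in% names(charges)))
  exp <- unlist(reference$dGhydExp)[ions]
  q <- charges[ions]
  if (is.null(Aq)) Aq <- unlist(reference$A1atm)[ions] * q
  d1 <- mu[ions] - exp
  d2 <- d1 + corr$cLR
  d3 <- d2 + corr$cWW
  led <- data.frame(ion = ions, dGhydExp = exp, dDG1 = d1, dDG2 = d2,
                    dDG3 = d3, dDG3minusAq = d3 - Aq[ions],
                    dDG3minusPhiQ = d3 - reference$phi * q,
                    row.names = NULL)
  printed <- led
  printed[-1] <- lapply(led[-1], round, digits = 1)
  list(ledger = led, printed = printed)
}

#' Difference in chemical potential between two ions
#'
#' @param muA,muB Chemical potentials (kcal/mol).
#' @param seA,seB Uncertainties, combined in quadrature.
#' @return List with `diff` and `se`.
#' @export
ionDifference <- function(muA, muB, seA = 0, seB = 0) {
  list(diff = muA - muB, se = sqrt(seA^2 + seB^2))
}

#' Electrolyte hydration free energy as a cation + anion sum
#'
#' Applies the same correction set to both ions before summing; charge-odd
#' corrections (`Aq`, `Phi q`, the sign of `C_BA`) enter with the signed
#' charge and therefore cancel between a +1 cation and a -1 anion when the
#' per-ion magnitudes match.
#'
#' @param muCation,muAnion Uncorrected chemical potentials (kcal/mol).
#' @param seCation,seAnion Uncertainties.
#' @param corrCation,corrAnion `correctionLedger`s for the two ions.
#' @param correction Which corrected value to sum: `"none"`, `"C1"`, `"C2"`
#'   or `"C3"`.
#' @return List with `sum` and `se` (quadrature).
#' @export
electrolyteSum <- function(muCation, muAnion, seCation = 0, seAnion = 0,
                           corrCation = NULL, corrAnion = NULL,
                           correction = c("none", "C1", "C2", "C3")) {
  correction <- match.arg(correction)
  add <- function(mu, corr) {
    if (correction == "none" || is.null(corr)) mu
    else mu + corr[[correction]]
  }
  list(sum = add(muCation, corrCation) + add(muAnion, corrAnion),
       se = sqrt(seCation^2 + seAnion^2))
}

#' Pressure profile of the chemical potential
#'
#' `dMu(P) = mu*(P) - mu*(1 atm)` with a natural cubic-spline interpolant
#' through the computed points (the spline is descriptive only).
#'
#' @param P Pressures (atm), including 1 atm.
#' @param mu Chemical potentials at `P` (kcal/mol).
#' @return List with the profile data frame and `interpolant`, a function of
#'   pressure.
#' @export
pressureProfile <- function(P, mu) {
  stopifnot(length(P) == length(mu), any(P == 1))
  o <- order(P)
  P <- P[o]; mu <- mu[o]
  dmu <- mu - mu[P == 1]
  list(profile = data.frame(P = P, dMu = dmu),
       interpolant = stats::splinefun(P, dmu, method = "natural"))
}

#' Linear excess-volume reference line
#'
#' `dMu_linear(P) = (P - 1) v*` converted from cm^3 atm/mol to kcal/mol
#' (1 cm^3 atm = 0.024217 cal).
#'
#' @param vStar Excess volume (cm^3/mol).
#' @param P Pressure grid (atm).
#' @return Data frame with `P` and `dMu` (kcal/mol).
#' @export
excessVolumeLine <- function(vStar, P) {
  data.frame(P = P, dMu = (P - 1) * vStar * kcalPerCm3Atm)
}
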