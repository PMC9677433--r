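## Free energy perturbation: Zwanzig exponential averaging, double-wide
## lambda-window schedules, block statistics and correlation diagnostics.
##
## Sign conventions.  A window at reference coupling lambda_ref yields two
## estimates: dgPlus = dG(lambda_ref -> lambda_ref + dLambda) and
## dgMinus = dG(lambda_ref -> lambda_ref - dLambda).  The total coupling free
## energy dG(0 -> 1) is the signed sum over the tiling:
## sum_i (dgPlus_i - dgMinus_i).

#' Zwanzig free-energy estimate from perturbation energies
#'
#' `dG = -(1/beta) log < exp(-beta dE) >` over samples of
#' `dE = E(perturbed) - E(reference)` evaluated on reference-ensemble
#' configurations (same coordinates and volume, so PV terms cancel in NPT).
#' Stabilised with the log-sum-exp shift.
#'
#' @param dE Numeric vector of perturbation energies (kcal/mol).
#' @param beta Inverse temperature 1/kT (mol/kcal).
#' @return Free-energy difference (kcal/mol).
#' @export
zwanzigEstimate <- function(dE, beta) {
  if (length(dE) == 0) stop("empty perturbation-energy sample")
  x <- -beta * dE
  m <- max(x)
  -(m + log(mean(exp(x - m)))) / beta
}

#' Double-wide lambda-window schedule
#'
#' Windows whose reference couplings and half-widths tile `[0, 1]` without
#' gaps: `nWindows` references at `(2k - 1) dLambda` with
#' `dLambda = 1 / (2 nWindows)`.  The defaults reproduce the production
#' protocol: 10 windows (increments of 0.05 in the coupled charge) for the
#' charge leg and 5 windows for LJ annihilation.
#'
#' @param leg `"charge"` (scales the ion charge at full LJ) or `"lj"` (scales
#'   the LJ solute at zero charge).
#' @param nWindows Number of double-wide windows.
#' @return Data frame with columns `lambdaRef`, `dLambda`, `leg`.
#' @export
windowSchedule <- function(leg = c("charge", "lj"),
                           nWindows = if (leg == "charge") 10 else 5) {
  leg <- match.arg(leg)
  dl <- 1 / (2 * nWindows)
  data.frame(lambdaRef = seq(dl, 1 - dl, by = 2 * dl), dLambda = dl,
             leg = leg)
}

#' Double-wide window estimate with block statistics
#'
#' Splits the per-trial perturbation energies into blocks of `blockSize`
#' samples, forms the Zwanzig estimate per block in both directions, and
#' reports block means with standard errors (at least 2 blocks are required
#' for an error estimate).
#'
#' @param dEminus,dEplus Perturbation energies toward `lambdaRef - dLambda`
#'   and `lambdaRef + dLambda`.
#' @param beta Inverse temperature (mol/kcal).
#' @param blockSize Samples per block.
#' @param lambdaRef,dLambda Window bookkeeping (optional).
#' @return Object of class `windowResult` with `dgMinus`, `dgPlus`, per-block
#'   values and standard errors.
#' @export
doubleWideWindow <- function(dEminus, dEplus, beta, blockSize,
                             lambdaRef = NA_real_, dLambda = NA_real_) {
  stopifnot(length(dEminus) == length(dEplus), blockSize >= 1)
  nb <- floor(length(dEplus) / blockSize)
  if (nb < 2) stop("need at least 2 blocks for an error estimate")
  idx <- rep(seq_len(nb), each = blockSize)
  keep <- seq_len(nb * blockSize)
  bM <- vapply(split(dEminus[keep], idx), zwanzigEstimate, numeric(1), beta)
  bP <- vapply(split(dEplus[keep], idx), zwanzigEstimate, numeric(1), beta)
  structure(list(
    lambdaRef = lambdaRef, dLambda = dLambda,
    dgMinus = mean(bM), dgPlus = mean(bP),
    seMinus = stats::sd(bM) / sqrt(nb), sePlus = stats::sd(bP) / sqrt(nb),
    blocksMinus = unname(bM), blocksPlus = unname(bP),
    blockSize = blockSize), class = "windowResult")
}

#' @export
print.windowResult <- function(x, ...) {
  cat(sprintf(paste0("<windowResult> lambdaRef = %.3f +/- %.3f: ",
                     "dG- = %.4f (%.4f), dG+ = %.4f (%.4f) kcal/mol ",
                     "[%d blocks]\n"),
              x$lambdaRef, x$dLambda, x$dgMinus, x$seMinus, x$dgPlus,
              x$sePlus, length(x$blocksPlus)))
  invisible(x)
}

#' Sum double-wide windows into a leg free energy
#'
#' The total is the signed sum over the tiling,
#' `sum(dgPlus - dgMinus)` for the coupling direction (0 -> 1), negated for
#' `direction = "decoupling"`.  Window uncertainties are combined in
#' quadrature assuming independent runs.
#'
#' @param results List of `windowResult` objects.
#' @param direction `"coupling"` or `"decoupling"`.
#' @return List with `dg`, `se` and the direction convention.
#' @export
sumWindows <- function(results, direction = c("coupling", "decoupling")) {
  direction <- match.arg(direction)
  dg <- sum(vapply(results, function(w) w$dgPlus - w$dgMinus, numeric(1)))
  se <- sqrt(sum(vapply(results, function(w) w$sePlus^2 + w$seMinus^2,
                        numeric(1))))
  if (direction == "decoupling") dg <- -dg
  list(dg = dg, se = se, direction = direction)
}

#' Assemble the chemical potential from its two legs
#'
#' `mu* = dG(0 -> LJ) + dG(LJ -> LJ + q)`; uncertainties combine in
#' quadrature.
#'
#' @param dgLJ,dgQ Leg free energies (kcal/mol).
#' @param seLJ,seQ Leg uncertainties.
#' @return Object of class `freeEnergyComponent`.
#' @export
freeEnergyComponent <- function(dgLJ, dgQ, seLJ = 0, seQ = 0) {
  structure(list(dgLJ = dgLJ, dgQ = dgQ, mu = dgLJ + dgQ,
                 seLJ = seLJ, seQ = seQ, seMu = sqrt(seLJ^2 + seQ^2)),
            class = "freeEnergyComponent")
}

#' @export
print.freeEnergyComponent <- function(x, ...) {
  cat(sprintf(paste0("<freeEnergyComponent> dG(0->LJ) = %.3f (%.3f), ",
                     "dG(LJ->LJ+q) = %.3f (%.3f), mu* = %.3f (%.3f) ",
                     "kcal/mol\n"),
              x$dgLJ, x$seLJ, x$dgQ, x$seQ, x$mu, x$seMu))
  invisible(x)
}

#' Statistical inefficiency of a sampled series
#'
#' For each block size `n_t`, `s(n_t) = n_t var(<x>_b) / var(x)` with the
#' variance of block means across the blocks that fit.  For uncorrelated
#' samples `s` stays near 1; for correlated samples it grows to a plateau
#' whose value estimates the correlation time (in samples).
#'
#' @param x Scalar time series.
#' @param blockSizes Block sizes in samples; each must allow at least 2
#'   blocks.
#' @return Data frame with columns `nt`, `s`, `nBlocks`.
#' @export
statisticalInefficiency <- function(x, blockSizes) {
  v <- stats::var(x)
  if (v == 0) stop("degenerate (constant) series: zero variance")
  rows <- lapply(blockSizes, function(nt) {
    nb <- floor(length(x) / nt)
    if (nb < 2)
      stop(sprintf("fewer than 2 blocks at block size %d", nt))
    m <- colMeans(matrix(x[seq_len(nb * nt)], nrow = nt))
    data.frame(nt = nt, s = nt * stats::var(m) / v, nBlocks = nb)
  })
  do.call(rbind, rows)
}

#' Correlation time from the plateau of the statistical inefficiency
#'
#' Fits `s(n_t) = tauCorr (1 - a / sqrt(n_t))` by weighted nonlinear least
#' squares; the asymptote `tauCorr` estimates the correlation time between
#' samples.  Each point is weighted by its block count: the sampling variance
#' of a variance-ratio estimate over `m` blocks scales as `2/(m - 1)`, so the
#' large-block points (few blocks, noisiest) are down-weighted.
#'
#' @param ineff Data frame from [statisticalInefficiency()].
#' @param startTau,startA Start values for the regression.
#' @return List with `tauCorr`, its standard error `tauSe`, coefficient `a`
#'   and the `nls` fit.
#' @export
fitPlateau <- function(ineff, startTau = max(ineff$s), startA = 1) {
  w <- if ("nBlocks" %in% names(ineff)) pmax(ineff$nBlocks - 1, 1)
       else rep(1, nrow(ineff))
  fit <- stats::nls(s ~ tau * (1 - a / sqrt(nt)), data = ineff,
                    weights = w, start = list(tau = startTau, a = startA))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  list(tauCorr = unname(co["tau"]), tauSe = unname(se),
       a = unname(co["a"]), fit = fit)
}

#' Run one double-wide FEP window with the compiled engine
#'
#' Equilibrates at the window's reference coupling, then collects
#' perturbation energies toward both neighbouring couplings during a
#' production run and forms the double-wide estimate with block statistics.
#'
#' @param window One row of a [windowSchedule()].
#' @param config Starting `configuration`.
#' @param ion,model,cutoffs,thermo,settings Simulation setup.
#' @param nEquil,nAvg Equilibration and production trials.
#' @param blockSize Block size in trials.
#' @param stride Perturbation-energy collection stride in trials.
#' @return List with the `windowResult` and the final configuration.
#' @export
runWindow <- function(window, config, ion, model, cutoffs, thermo, settings,
                      nEquil, nAvg, blockSize, stride = 10L) {
  lam <- window$lambdaRef; dl <- window$dLambda
  if (lam - dl < -1e-12 || lam + dl > 1 + 1e-12)
    stop("perturbed coupling outside [0, 1]")
  if (window$leg == "charge") {
    ref <- couplingState(1, lam)
    pert <- rbind(c(1, max(lam - dl, 0)), c(1, min(lam + dl, 1)))
  } else {
    ref <- couplingState(lam, 0)
    pert <- rbind(c(max(lam - dl, 0), 0), c(min(lam + dl, 1), 0))
  }
  eq <- runMC(config, ion, ref, thermo, settings, nEquil, model, cutoffs)
  pr <- runMC(eq$config, ion, ref, thermo, settings, nAvg, model, cutoffs,
              perturb = pert, stride = stride)
  res <- doubleWideWindow(pr$dE[, 1], pr$dE[, 2], thermo$beta,
                          blockSize = max(2, floor(blockSize / stride)),
                          lambdaRef = lam, dLambda = dl)
  list(result = res, config = pr$config)
}

#' Run a full FEP leg over a window schedule
#'
#' Convenience driver: runs every window of the schedule sequentially
#' (passing the final configuration of one window to the next) and sums the
#' double-wide estimates into the leg free energy.
#'
#' @inheritParams runWindow
#' @param schedule A [windowSchedule()].
#' @return List with `dg`, `se`, the per-window results and the final
#'   configuration.
#' @export
runLeg <- function(schedule, config, ion, model, cutoffs, thermo, settings,
                   nEquil, nAvg, blockSize, stride = 10L) {
  results <- vector("list", nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    out <- runWindow(schedule[k, ], config, ion, model, cutoffs, thermo,
                     settings, nEquil, nAvg, blockSize, stride)
    results[[k]] <- out$result
    config <- out$config
  }
  tot <- sumWindows(results)
  list(dg = tot$dg, se = tot$se, windows = results, config = config)
}
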