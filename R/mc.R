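## NPT Metropolis Monte Carlo.  Two surfaces are provided:
##  - generic single-move functions taking an arbitrary energy function, used
##    for toy systems and property tests (detailed balance, ideal-gas volume
##    statistics, Boltzmann-distribution checks);
##  - a fast compiled run loop for the real ion + rigid-water force field,
##    with incremental energy bookkeeping, periodic from-scratch verification
##    and perturbation-energy collection hooks for FEP.

#' Thermodynamic state for NPT sampling
#'
#' @param T Temperature (K).
#' @param P Pressure (atm).
#' @return Object of class `thermoState` with `beta` = 1/kT in mol/kcal.
#' @export
thermoState <- function(T = 298.15, P = 1) {
  stopifnot(T > 0, P > 0)
  structure(list(T = T, P = P, beta = 1 / (kBoltzmann * T)),
            class = "thermoState")
}

#' Monte Carlo move settings
#'
#' @param maxTrans Maximum translation per move (Angstrom).
#' @param maxRot Maximum rotation per move (rad).
#' @param maxVol Maximum volume change per volume move (Angstrom^3); volume is
#'   sampled linearly in V, so the acceptance weight carries the
#'   `N log(V'/V)` Jacobian term.
#' @param pVolMove Probability that a trial is a volume move; the remainder
#'   are combined translation+rotation moves of one random water (the ion is
#'   never selected).
#' @return Object of class `moveSettings`.
#' @export
moveSettings <- function(maxTrans = 0.15, maxRot = 0.25, maxVol = 150,
                         pVolMove = 0.02) {
  stopifnot(maxTrans > 0, maxRot > 0, maxVol > 0,
            pVolMove >= 0, pVolMove <= 1)
  structure(list(maxTrans = maxTrans, maxRot = maxRot, maxVol = maxVol,
                 pVolMove = pVolMove), class = "moveSettings")
}

#' Attempt one particle move (generic energy function)
#'
#' Picks one random water, proposes a combined random translation and rigid
#' rotation, and accepts with the Metropolis probability
#' `min(1, exp(-beta dU))`, where `dU = energyFn(config') - energyFn(config)`.
#' Rejection restores the prior state exactly.  The ion is never moved.
#'
#' @param config A `configuration`.
#' @param thermo A `thermoState`.
#' @param settings A `moveSettings`.
#' @param energyFn Function `configuration -> energy (kcal/mol)`.
#' @return List with elements `config`, `accepted`, `dU`.
#' @export
attemptParticleMove <- function(config, thermo, settings, energyFn) {
  n <- nWaters(config)
  stopifnot(n > 0)
  i <- sample.int(n, 1)
  eOld <- energyFn(config)
  prop <- config
  prop$positions[i, ] <- wrapCoords(
    config$positions[i, ] + stats::runif(3, -1, 1) * settings$maxTrans,
    config$L)
  prop$quaternions[i, ] <- randomRotationQuat(settings$maxRot,
                                              config$quaternions[i, ])
  dU <- energyFn(prop) - eOld
  accepted <- dU <= 0 || stats::runif(1) < exp(-thermo$beta * dU)
  list(config = if (accepted) prop else config, accepted = accepted, dU = dU)
}

#' Attempt one volume move (generic energy function)
#'
#' Proposes `V' = V + delta` with `delta` uniform in
#' `[-maxVol, maxVol]` (linear sampling in V), scales the water oxygen
#' positions by `(V'/V)^(1/3)` keeping the internal geometry rigid and the ion
#' at the center, and accepts with probability
#' `min(1, exp(-beta [dU + P dV - N kT log(V'/V)]))`.
#' A proposal with `V' <= 0` is rejected outright.
#'
#' @inheritParams attemptParticleMove
#' @return List with elements `config`, `accepted`, `dU`.
#' @export
attemptVolumeMove <- function(config, thermo, settings, energyFn) {
  V <- config$L^3
  Vn <- V + stats::runif(1, -1, 1) * settings$maxVol
  if (Vn <= 0)
    return(list(config = config, accepted = FALSE, dU = NA_real_))
  s <- (Vn / V)^(1 / 3)
  prop <- config
  prop$L <- config$L * s
  prop$positions <- config$positions * s
  dU <- energyFn(prop) - energyFn(config)
  n <- nWaters(config)
  w <- dU + thermo$P * atmPerKcalA3 * (Vn - V) -
    n * kBoltzmann * thermo$T * log(Vn / V)
  accepted <- w <= 0 || stats::runif(1) < exp(-thermo$beta * w)
  list(config = if (accepted) prop else config, accepted = accepted, dU = dU)
}

randomRotationQuat <- function(maxRot, quat) {
  ax <- stats::rnorm(3)
  n <- sqrt(sum(ax^2))
  if (n < 1e-12) { ax <- c(1, 0, 0); n <- 1 }
  ang <- stats::runif(1, -1, 1) * maxRot
  dq <- c(cos(ang / 2), sin(ang / 2) * ax / n)
  out <- quatMultiply(dq, quat)
  out / sqrt(sum(out^2))
}

quatMultiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Run the compiled NPT Monte Carlo engine
#'
#' Evolves a configuration of one fixed ion plus rigid waters under the
#' packaged force field, maintaining the total energy incrementally and
#' verifying it against a from-scratch recomputation every `checkInterval`
#' trials (aborting if the drift exceeds `driftTol`).  Optionally collects
#' ion-water perturbation energies `dE = U_ion(lambda') - U_ion(lambda_ref)`
#' at the rows of `perturb` every `stride` trials for FEP estimation; the
#' perturbed states share the sampled coordinates and volume of the reference
#' state, so PV terms cancel in the NPT Zwanzig average.
#'
#' Runs are reproducible: the engine draws from R's RNG stream, so
#' `set.seed()` before the call fixes the trajectory.
#'
#' @param config A `configuration`.
#' @param ion An `ionSpec`.
#' @param coupling Reference `couplingState`.
#' @param thermo A `thermoState`.
#' @param settings A `moveSettings`.
#' @param nTrials Number of Monte Carlo trials.
#' @param model,cutoffs Water model and cutoff scheme.
#' @param perturb Optional matrix with columns (lambdaLJ, lambdaQ) of
#'   perturbed couplings for FEP collection.
#' @param stride Collection stride in trials (0 disables collection).
#' @param sampleStride Stride for the energy/volume traces.
#' @param checkInterval Trials between full-energy verification checks.
#' @param driftTol Bookkeeping tolerance (kcal/mol).
#' @return List with the final `config`, a `runStats` record (acceptance
#'   counts and ratios, energy/volume traces, `maxDrift`) and the collected
#'   `dE` matrix (one column per row of `perturb`).
#' @export
runMC <- function(config, ion, coupling, thermo, settings, nTrials,
                  model, cutoffs, perturb = NULL, stride = 0L,
                  sampleStride = 1000L, checkInterval = 25000L,
                  driftTol = 1e-6) {
  checkCutoffs(cutoffs, config$L)
  if (is.null(perturb)) perturb <- matrix(numeric(0), ncol = 2)
  if (any(perturb < 0 | perturb > 1))
    stop("perturbed coupling outside [0, 1]")
  out <- cppRunMC(config$positions, config$quaternions, config$L,
                  .ffPack(model), cutoffs$rIW, cutoffs$rWW,
                  ion$charge, ion$sigma, ion$eps,
                  coupling$lambdaLJ, coupling$lambdaQ,
                  thermo$T, thermo$P, as.integer(nTrials),
                  settings$maxTrans, settings$maxRot, settings$maxVol,
                  settings$pVolMove, perturb,
                  as.integer(stride), as.integer(sampleStride),
                  as.integer(checkInterval), driftTol)
  final <- newConfiguration(out$L, out$positions, out$quaternions, ion)
  stats <- structure(list(
    nTrials = nTrials,
    accTrans = out$accTrans, nTrans = out$nTrans,
    accVol = out$accVol, nVol = out$nVol,
    transRatio = if (out$nTrans > 0) out$accTrans / out$nTrans else NA_real_,
    volRatio = if (out$nVol > 0) out$accVol / out$nVol else NA_real_,
    energyTrace = out$energyTrace, volumeTrace = out$volumeTrace,
    finalEnergy = out$energy, maxDrift = out$maxDrift), class = "runStats")
  list(config = final, stats = stats, dE = out$dE)
}

#' @export
print.runStats <- function(x, ...) {
  cat(sprintf(paste0("<runStats> %d trials; acceptance: particle %.1f%% ",
                     "(%.0f/%.0f), volume %.1f%% (%.0f/%.0f); ",
                     "max drift %.2e\n"),
              x$nTrials, 100 * x$transRatio, x$accTrans, x$nTrans,
              100 * x$volRatio, x$accVol, x$nVol, x$maxDrift))
  invisible(x)
}

#' Tune move amplitudes toward a target acceptance ratio
#'
#' Runs short equilibration chunks, scaling the translation/rotation and
#' volume amplitudes after each chunk so both acceptance ratios approach the
#' target (standard practice; amplitudes are then frozen for production).
#'
#' @inheritParams runMC
#' @param nChunks,chunkTrials Number and length of tuning chunks.
#' @param target Target acceptance ratio.
#' @return List with the equilibrated `config` and tuned `settings`.
#' @export
tuneMoves <- function(config, ion, coupling, thermo, settings, model, cutoffs,
                      nChunks = 10, chunkTrials = 2000, target = 0.4) {
  for (k in seq_len(nChunks)) {
    out <- runMC(config, ion, coupling, thermo, settings, chunkTrials,
                 model, cutoffs, checkInterval = 0L, sampleStride = 0L)
    config <- out$config
    s <- out$stats
    adj <- function(amp, ratio)
      if (is.na(ratio)) amp else max(amp * exp(ratio - target), amp * 0.2)
    settings <- moveSettings(
      maxTrans = min(adj(settings$maxTrans, s$transRatio), config$L / 4),
      maxRot = min(adj(settings$maxRot, s$transRatio), pi),
      maxVol = min(adj(settings$maxVol, s$volRatio), config$L^3 / 10),
      pVolMove = settings$pVolMove)
  }
  list(config = config, settings = settings)
}
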