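## Configuration files, XYZ snapshots and synthetic-data generators, so every
## module is exercisable without any external dataset.

#' Run configuration
#'
#' A fully serialisable description of one simulation/analysis run; a run is
#' reproducible from the configuration plus its seed alone.
#'
#' @param ion Ion name (must exist in the force-field file).
#' @param T,P Thermodynamic state (K, atm).
#' @param nWaters Number of waters.
#' @param rIW,rWW Cutoffs (Angstrom).
#' @param chargeWindows,ljWindows Window counts of the two legs.
#' @param nEquil,nAvg,blockSize Trial counts per window and block size.
#' @param seed RNG seed.
#' @param rLR,cavityN Cavity radius (Angstrom) and surface-point count for
#'   the continuum corrections.
#' @param forcefieldFile,referenceFile Parameter/constant file paths (`NULL`
#'   for the packaged defaults).
#' @return Object of class `runConfig`.
#' @export
runConfig <- function(ion = "K+", T = 298.15, P = 1, nWaters = 512,
                      rIW = 11.5, rWW = 11.5, chargeWindows = 10,
                      ljWindows = 5, nEquil = 10e6, nAvg = 20e6,
                      blockSize = 2e6, seed = 1, rLR = 13.2, cavityN = 1000,
                      forcefieldFile = NULL, referenceFile = NULL) {
  structure(list(ion = ion, T = T, P = P, nWaters = nWaters, rIW = rIW,
                 rWW = rWW, chargeWindows = chargeWindows,
                 ljWindows = ljWindows, nEquil = nEquil, nAvg = nAvg,
                 blockSize = blockSize, seed = seed, rLR = rLR,
                 cavityN = cavityN, forcefieldFile = forcefieldFile,
                 referenceFile = referenceFile),
            class = "runConfig")
}

#' Write / read a run configuration (JSON)
#'
#' @param config A `runConfig`.
#' @param path File path.
#' @return `readRunConfig` returns the `runConfig`; `writeRunConfig` its path
#'   invisibly.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(x) if (is.integer(x)) as.numeric(x) else x)
  do.call(runConfig, raw[!vapply(raw, is.null, logical(1))])
}

#' Write a configuration as an XYZ snapshot
#'
#' All sites are written (ion first, then O/H/H/M per water); the comment
#' line carries the box length and ion label so the file is self-describing.
#'
#' @param config A `configuration`.
#' @param model A `waterModel`.
#' @param path File path.
#' @export
writeXYZ <- function(config, model, path) {
  n <- nWaters(config)
  lines <- c(sprintf("%d", 1 + 4 * n),
             sprintf("L= %.10f ion= %s", config$L,
                     if (!is.null(config$ion)) config$ion$name else "none"),
             sprintf("%-2s %18.10f %18.10f %18.10f", "X", 0, 0, 0))
  labs <- c("O", "H", "H", "M")
  for (i in seq_len(n)) {
    s <- waterSites(config$positions[i, ], config$quaternions[i, ], model)
    lines <- c(lines, sprintf("%-2s %18.10f %18.10f %18.10f",
                              labs, s[, 1], s[, 2], s[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from an XYZ snapshot
#'
#' Reconstructs each water's rigid-body description (oxygen position and
#' orientation quaternion) from its O/H/H sites.
#'
#' @param path File path.
#' @param model A `waterModel`.
#' @param forcefield Optional force field to resolve the ion label.
#' @return A `configuration`.
#' @export
readXYZ <- function(path, model, forcefield = NULL) {
  lines <- readLines(path)
  nAtoms <- as.integer(lines[1])
  hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  L <- as.numeric(hdr[which(hdr == "L=") + 1])
  ionName <- hdr[which(hdr == "ion=") + 1]
  coords <- do.call(rbind, lapply(strsplit(trimws(
    lines[3:(2 + nAtoms)]), "\\s+"), function(x) as.numeric(x[2:4])))
  n <- (nAtoms - 1) / 4
  stopifnot(n == floor(n))
  pos <- matrix(0, n, 3)
  quat <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    base <- 1 + 4 * (i - 1)
    O <- coords[base + 1, ]; H1 <- coords[base + 2, ]; H2 <- coords[base + 3, ]
    pos[i, ] <- O
    quat[i, ] <- orientationFromSites(O, H1, H2, model)
  }
  ion <- if (!is.null(forcefield) && ionName %in% names(forcefield$ions))
    forcefield$ions[[ionName]] else NULL
  newConfiguration(L, pos, quat, ion)
}

## quaternion of the rotation mapping the molecular frame onto the lab frame
orientationFromSites <- function(O, H1, H2, model) {
  zRef <- (model$siteOffsets["H1", ] + model$siteOffsets["H2", ])
  zRef <- zRef / sqrt(sum(zRef^2))
  xRef <- model$siteOffsets["H1", ] - model$siteOffsets["H2", ]
  xRef <- xRef / sqrt(sum(xRef^2))
  zLab <- (H1 - O) + (H2 - O); zLab <- zLab / sqrt(sum(zLab^2))
  xLab <- (H1 - O) - (H2 - O); xLab <- xLab / sqrt(sum(xLab^2))
  yRef <- crossProd(zRef, xRef)
  yLab <- crossProd(zLab, xLab)
  R <- cbind(xLab, yLab, zLab) %*% t(cbind(xRef, yRef, zRef))
  matrixToQuat(R)
}

crossProd <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

matrixToQuat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Generate a random water box around the fixed ion
#'
#' Places `N` waters with random orientations at the requested number
#' density, rejecting placements whose O-O or ion-O distance falls below a
#' hard-core threshold.  The box length is set from the density exactly:
#' `L = (N / density)^(1/3)`.  Deterministic per seed.
#'
#' @param N Number of waters.
#' @param density Target number density (Angstrom^-3); default is the water
#'   model's 1-atm value.
#' @param seed RNG seed.
#' @param model A `waterModel`.
#' @param ion Optional `ionSpec` carried in the configuration.
#' @param minDist Hard-core rejection distance (Angstrom).
#' @return A `configuration`.
#' @export
generateWaterBox <- function(N, density = model$numberDensity1atm, seed = 1,
                             model = waterModel(), ion = NULL,
                             minDist = 2.4) {
  set.seed(seed)
  L <- if (N > 0) (N / density)^(1 / 3) else 10
  pos <- matrix(0, N, 3)
  quat <- matrix(0, N, 4)
  placed <- 0
  tries <- 0
  while (placed < N) {
    tries <- tries + 1
    if (tries > 2e5) stop("could not place waters at the requested density")
    p <- stats::runif(3, -L / 2, L / 2)
    if (sqrt(sum(p^2)) < minDist) next
    if (placed > 0) {
      d <- sweep(pos[seq_len(placed), , drop = FALSE], 2, p, `-`)
      d <- wrapCoords(d, L)
      if (min(sqrt(rowSums(d^2))) < minDist) next
    }
    placed <- placed + 1
    pos[placed, ] <- p
    quat[placed, ] <- randomQuat()
  }
  newConfiguration(L, pos, quat, ion)
}

randomQuat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

#' Synthetic charging curve with known ground truth
#'
#' `dG(lambda q) = A lambda q + B (lambda q)^2 + noise`, the fixture for
#' charge-scaling fit recovery tests.
#'
#' @param A,B True coefficients (kcal/(mol e), kcal/(mol e^2)).
#' @param lambdaGrid Coupled-charge grid (e).
#' @param noiseSd Gaussian noise s.d. (kcal/mol).
#' @param seed RNG seed.
#' @param ion,P Labels.
#' @return A `chargingCurve` with attribute `truth = c(A, B)`.
#' @export
generateSyntheticChargingCurve <- function(A, B, lambdaGrid = seq(0.1, 1,
                                                                  by = 0.1),
                                           noiseSd = 0, seed = 1,
                                           ion = NA_character_,
                                           P = NA_real_) {
  set.seed(seed)
  dg <- A * lambdaGrid + B * lambdaGrid^2 +
    stats::rnorm(length(lambdaGrid), 0, noiseSd)
  out <- chargingCurve(lambdaGrid, dg,
                       se = if (noiseSd > 0)
                         rep(noiseSd, length(lambdaGrid)) else NULL,
                       ion = ion, P = P)
  attr(out, "truth") <- c(A = A, B = B)
  out
}

#' Stationary AR(1) series with known statistical inefficiency
#'
#' `x_t = phi x_(t-1) + e_t` with unit-variance stationary initialisation;
#' the exact statistical inefficiency is `(1 + phi) / (1 - phi)`.
#'
#' @param phi Autoregression coefficient, `|phi| < 1`.
#' @param n Series length.
#' @param seed RNG seed.
#' @return Numeric vector with attribute `inefficiency`.
#' @export
generateAR1Series <- function(phi, n, seed = 1) {
  stopifnot(abs(phi) < 1)
  set.seed(seed)
  x1 <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, 0, sqrt(1 - phi^2))
  x <- c(x1, as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = x1)))
  attr(x, "inefficiency") <- (1 + phi) / (1 - phi)
  x
}
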