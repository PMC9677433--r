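# Independent pure-R site-site energy oracle and small fixtures.  The oracle
# deliberately shares no code with the package kernels: explicit double loops
# over molecules and sites, with the same molecule-based minimum-image and
# truncation conventions.

kC <- 332.06
kB <- 1.9872041e-3

oracleSites <- function(config, model, i) {
  waterSites(config$positions[i, ], config$quaternions[i, ], model)
}

oracleLJ <- function(sigma, eps, r) {
  if (sigma == 0 || eps == 0) return(0)
  4 * eps * ((sigma / r)^12 - (sigma / r)^6)
}

# water-water: loop over pairs, image shift keyed to O-O, all-or-nothing
oracleWW <- function(config, model, cutoffs) {
  n <- nWaters(config)
  if (n < 2) return(0)
  e <- 0
  chg <- model$siteCharges
  for (i in seq_len(n - 1)) {
    si <- oracleSites(config, model, i)
    for (j in (i + 1):n) {
      d <- config$positions[j, ] - config$positions[i, ]
      dm <- d - config$L * round(d / config$L)
      r <- sqrt(sum(dm^2))
      if (r >= cutoffs$rWW) next
      shift <- dm - d
      sj <- sweep(oracleSites(config, model, j), 2, shift, `+`)
      e <- e + oracleLJ(model$sigmaO, model$epsO, r)
      for (a in 2:4) for (b in 2:4) {
        e <- e + kC * chg[a] * chg[b] / sqrt(sum((sj[b, ] - si[a, ])^2))
      }
    }
  }
  e
}

# ion at the origin; coupling scales the ion parameters linearly
oracleIW <- function(config, ion, coupling, model, cutoffs) {
  n <- nWaters(config)
  e <- 0
  chg <- model$siteCharges
  sigma <- sqrt(coupling$lambdaLJ * ion$sigma * model$sigmaO)
  eps <- sqrt(coupling$lambdaLJ * ion$eps * model$epsO)
  qe <- coupling$lambdaQ * ion$charge
  for (i in seq_len(n)) {
    d <- config$positions[i, ]
    dm <- d - config$L * round(d / config$L)
    r <- sqrt(sum(dm^2))
    if (r >= cutoffs$rIW) next
    shift <- dm - d
    si <- sweep(oracleSites(config, model, i), 2, shift, `+`)
    e <- e + oracleLJ(sigma, eps, r)
    for (a in 2:4) e <- e + kC * qe * chg[a] / sqrt(sum(si[a, ]^2))
  }
  e
}

oracleTotal <- function(config, ion, coupling, model, cutoffs) {
  oracleWW(config, model, cutoffs) +
    oracleIW(config, ion, coupling, model, cutoffs)
}

# small shared fixtures
ffFixture <- loadForcefield()
tip4p <- ffFixture$water
kIon <- ffFixture$ions[["K+"]]
brIon <- ffFixture$ions[["Br-"]]

smallBox <- function(N = 16, seed = 42, ion = kIon) {
  generateWaterBox(N, seed = seed, model = tip4p, ion = ion)
}
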