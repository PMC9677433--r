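# NPT Metropolis engine: acceptance rule, determinism, bookkeeping, and the
# analytic ideal-gas volume distribution under linear-V sampling.

nullWater <- waterModel(qH = 0, qM = 0, epsO = 0, name = "ideal")

test_that("particle moves always accept dU = 0 and effectively never accept huge dU", {
  set.seed(1)
  cfg <- smallBox(4, seed = 5)
  th <- thermoState()
  st <- moveSettings()
  accFlat <- replicate(50, attemptParticleMove(cfg, th, st,
                                               function(c) 0)$accepted)
  expect_true(all(accFlat))
  # overlap-like proposal: energy jumps by +1e8 whenever anything moves
  hard <- function(c)
    if (identical(c$positions, cfg$positions)) 0 else 1e8
  accHard <- replicate(50, attemptParticleMove(cfg, th, st, hard)$accepted)
  expect_false(any(accHard))
})

test_that("Metropolis sampling reproduces Boltzmann occupancies (two-level energy)", {
  # one water whose x-position selects an energy level: E = c for x > 0.
  # Detailed balance => P(x > 0) / P(x <= 0) = exp(-beta c).
  set.seed(42)
  cfg <- newConfiguration(10, matrix(c(-2, 0, 0), 1, 3),
                          matrix(c(1, 0, 0, 0), 1, 4))
  th <- thermoState(T = 298.15)
  st <- moveSettings(maxTrans = 4, maxRot = 0.5)
  cLevel <- 0.4  # kcal/mol
  eFn <- function(c) if (c$positions[1, 1] > 0) cLevel else 0
  nUp <- 0L; nTot <- 20000L
  for (k in seq_len(nTot)) {
    out <- attemptParticleMove(cfg, th, st, eFn)
    cfg <- out$config
    if (cfg$positions[1, 1] > 0) nUp <- nUp + 1L
  }
  ratio <- nUp / (nTot - nUp)
  expect_equal(ratio, exp(-th$beta * cLevel), tolerance = 0.08)
})

test_that("two soft-repulsive particles match direct quadrature of the Boltzmann distribution", {
  # pair density for r < L/2 in cubic PBC is 4 pi r^2 exp(-beta u(r)) / Z
  set.seed(99)
  L <- 8
  cfg <- newConfiguration(L, rbind(c(-1, 0, 0), c(1.5, 0, 0)),
                          rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  th <- thermoState()
  st <- moveSettings(maxTrans = 1.6, maxRot = 0.5)
  sig <- 2.4
  u <- function(r) (sig / r)^12
  eFn <- function(c) {
    d <- c$positions[2, ] - c$positions[1, ]
    d <- d - c$L * round(d / c$L)
    u(sqrt(sum(d^2)))
  }
  rs <- numeric(40000)
  for (k in seq_along(rs)) {
    out <- attemptParticleMove(cfg, th, st, eFn)
    cfg <- out$config
    d <- cfg$positions[2, ] - cfg$positions[1, ]
    d <- d - L * round(d / L)
    rs[k] <- sqrt(sum(d^2))
  }
  rs <- rs[-(1:2000)]
  breaks <- seq(0, L / 2, length.out = 9)
  keep <- rs < L / 2
  obs <- tabulate(cut(rs[keep], breaks, labels = FALSE), nbins = 8)
  dens <- function(r) 4 * pi * r^2 * exp(-th$beta * u(r))
  probs <- vapply(seq_len(8), function(b)
    stats::integrate(dens, breaks[b], breaks[b + 1])$value, numeric(1))
  probs <- probs / sum(probs)
  expFrac <- probs
  obsFrac <- obs / sum(obs)
  expect_lt(max(abs(obsFrac - expFrac)), 0.025)
})

test_that("ideal-gas NPT volume average is (N+1)kT/P under linear-V sampling", {
  set.seed(2024)
  N <- 32
  cfg <- generateWaterBox(N, seed = 8, model = nullWater)
  th <- thermoState(T = 298.15, P = 1000)  # higher P keeps <V> modest
  kT <- 1 / th$beta
  vExp <- (N + 1) * kT / (th$P * ionhyd:::atmPerKcalA3)
  st <- moveSettings(maxTrans = 1, maxRot = 1, maxVol = 0.35 * vExp,
                     pVolMove = 1)
  out <- runMC(cfg, kIon, couplingState(0, 0), th, st, 60000,
               nullWater, cutoffScheme(0.5, 0.5),
               sampleStride = 5L, checkInterval = 0L)
  v <- out$stats$volumeTrace
  v <- v[-(1:2000)]
  se <- stats::sd(v) / sqrt(length(v) / 50)  # generous correlation allowance
  expect_lt(abs(mean(v) - vExp), 5 * se)
  # doubling P halves <V>
  th2 <- thermoState(T = 298.15, P = 2000)
  st2 <- moveSettings(maxTrans = 1, maxRot = 1, maxVol = 0.35 * vExp / 2,
                      pVolMove = 1)
  out2 <- runMC(out$config, kIon, couplingState(0, 0), th2, st2, 60000,
                nullWater, cutoffScheme(0.5, 0.5),
                sampleStride = 5L, checkInterval = 0L)
  v2 <- out2$stats$volumeTrace
  v2 <- v2[-(1:2000)]
  expect_equal(mean(v2) / mean(v), 0.5, tolerance = 0.06)
})

test_that("zero-amplitude volume moves keep the volume fixed, V' <= 0 auto-rejects", {
  cfg <- smallBox(4, seed = 6)
  th <- thermoState()
  set.seed(3)
  out <- attemptVolumeMove(cfg, th, moveSettings(maxVol = 1e-12),
                           function(c) 0)
  expect_equal(out$config$L, cfg$L, tolerance = 1e-6)
  big <- moveSettings(maxVol = cfg$L^3 * 50)
  rejected <- FALSE
  for (k in 1:200) {
    o <- attemptVolumeMove(cfg, th, big, function(c) 0)
    if (!o$accepted && is.na(o$dU)) rejected <- TRUE
  }
  expect_true(rejected)  # V' <= 0 proposals occurred and were auto-rejected
})

test_that("engine trajectories are reproducible for a fixed seed and bookkeeping drift stays tiny", {
  cfg <- smallBox(12, seed = 31)
  cut <- cutoffScheme(cfg$L / 2 * 0.99, cfg$L / 2 * 0.99)
  th <- thermoState()
  st <- moveSettings(maxVol = 25)
  run <- function() {
    set.seed(555)
    runMC(cfg, kIon, couplingState(1, 1), th, st, 20000, tip4p, cut,
          sampleStride = 100L, checkInterval = 2000L, driftTol = 1e-8)
  }
  a <- run(); b <- run()
  expect_identical(a$stats$energyTrace, b$stats$energyTrace)
  expect_identical(a$config$positions, b$config$positions)
  expect_lt(a$stats$maxDrift, 1e-8)
  # final incremental energy agrees with a from-scratch recomputation
  expect_equal(a$stats$finalEnergy,
               totalEnergy(a$config, kIon, couplingState(1, 1), tip4p, cut),
               tolerance = 1e-8)
})

test_that("move amplitude tuning drives particle acceptance toward the target", {
  set.seed(17)
  cfg <- smallBox(12, seed = 13)
  cut <- cutoffScheme(cfg$L / 2 * 0.99, cfg$L / 2 * 0.99)
  th <- thermoState()
  tuned <- tuneMoves(cfg, kIon, couplingState(1, 1), th,
                     moveSettings(maxTrans = 2, maxRot = 2, maxVol = 60),
                     tip4p, cut, nChunks = 8, chunkTrials = 3000)
  out <- runMC(tuned$config, kIon, couplingState(1, 1), th, tuned$settings,
               10000, tip4p, cut, checkInterval = 0L)
  expect_gt(out$stats$transRatio, 0.25)
  expect_lt(out$stats$transRatio, 0.55)
})
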