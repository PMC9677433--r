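# Continuum-electrostatics corrections: Born closed form, the tessellated
# apparent-surface-charge solver, and the truncation corrections C_WW / C_BA.

test_that("Born energy: vacuum limit, conductor limit, and the cavity used in production", {
  expect_identical(bornEnergy(1, 13.2, 1), 0)
  # production cavity with the 1-atm dielectric constant of water
  expect_equal(round(bornEnergy(1, 13.2, 78.4), 2), -12.42)
  # conductor limit -kC / 2R
  expect_equal(bornEnergy(1, 13.2, 1e12), -332.06 / (2 * 13.2),
               tolerance = 1e-9)
  expect_equal(round(-332.06 / (2 * 13.2), 2), -12.58)
  expect_error(bornEnergy(1, 13.2, 0.5), "permittivity")
  expect_error(bornEnergy(1, -1, 78.4))
})

test_that("long-range correction C_LR: delta = 0 reduces to Born at the cutoff; 1/R scaling", {
  expect_equal(cLR(1, 11.5, 0, 78.4), bornEnergy(1, 11.5, 78.4))
  expect_equal(round(cLR(1, 11.5, 1.7, 78.4), 2), -12.42)
  # doubling R_LR halves the magnitude
  expect_equal(cLR(1, 11.5, 1.7, 78.4) / cLR(1, 24.7, 1.7, 78.4), 2,
               tolerance = 1e-12)
})

test_that("tessellation is deterministic, on-sphere, equal-area and quasi-uniform", {
  cav <- tessellateSphere(1000, 13.2)
  expect_equal(sqrt(rowSums(cav$points^2)), rep(13.2, 1000),
               tolerance = 1e-9)
  expect_equal(sum(cav$areas), 4 * pi * 13.2^2, tolerance = 1e-9)
  expect_identical(cav$points, tessellateSphere(1000, 13.2)$points)
  # nearest-neighbour spacing is quasi-uniform (no clustering)
  nn <- vapply(seq(1, 1000, by = 20), function(k) {
    d <- sqrt(colSums((t(cav$points) - cav$points[k, ])^2))
    min(d[d > 0])
  }, numeric(1))
  expect_lt(max(nn) / min(nn), 2)
})

test_that("surface-charge solve: zero charge, Gauss law, near-uniform charges by symmetry", {
  cav <- tessellateSphere(1000, 13.2)
  Tm <- buildT(cav, 78.4, closure = "cap")
  expect_identical(solveCharges(Tm, 0)$charges, rep(0, 1000))
  ch <- solveCharges(Tm, 1)
  gauss <- -(1 - 1 / 78.4)
  expect_equal(sum(ch$charges), gauss, tolerance = 0.01)
  # central-charge problem: all surface charges equal up to tessellation noise
  expect_lt((max(ch$charges) - min(ch$charges)) / abs(mean(ch$charges)),
            0.01)
  # negative central charge flips the sign
  expect_equal(solveCharges(Tm, -1)$charges, -ch$charges, tolerance = 1e-12)
})

test_that("dG_q converges to the Born formula as the tessellation refines", {
  born <- bornEnergy(1, 13.2, 78.4)
  relErr <- function(n, closure) {
    cav <- tessellateSphere(n, 13.2)
    abs(dgQ(solveCharges(buildT(cav, 78.4, closure = closure), 1)) - born) /
      abs(born)
  }
  errCap <- vapply(c(100, 250, 500, 1000), relErr, numeric(1), "cap")
  expect_true(all(diff(errCap) < 0))      # monotone decrease
  expect_lt(errCap[4], 0.005)             # within 0.5% at n = 1000
  # the classical local closure also converges monotonically, but carries a
  # larger finite-n bias (the published corrections are defined under it)
  errLoc <- vapply(c(100, 250, 500, 1000), relErr, numeric(1), "local")
  expect_true(all(diff(errLoc) < 0))
})

test_that("C_WW reproduces the published correction table at n = 1000", {
  # rows: cavity radius R_LR; columns: T-matrix cutoff 10 and 11.5 A
  tbl <- rbind(c(10.0, 5.63, 4.55),
               c(11.5, 5.79, 4.89),
               c(13.2, 5.78, 5.03))
  for (r in seq_len(nrow(tbl))) {
    expect_equal(cWW(tbl[r, 1], 78.4, 10), tbl[r, 2], tolerance = 0.1,
                 expected.label = sprintf("C_WW(R=%.1f, cut=10)", tbl[r, 1]))
    expect_equal(cWW(tbl[r, 1], 78.4, 11.5), tbl[r, 3], tolerance = 0.1,
                 expected.label = sprintf("C_WW(R=%.1f, cut=11.5)",
                                          tbl[r, 1]))
  }
})

test_that("C_WW is positive, non-increasing in the cutoff, zero beyond 2R, and scales as q^2", {
  vals <- vapply(c(8, 10, 11.5, 14), function(cc) cWW(13.2, 78.4, cc, n = 500),
                 numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) < 0))
  expect_equal(cWW(13.2, 78.4, 27, n = 500), 0, tolerance = 1e-9)
  # q^2 scaling: correction at half charge is a quarter of the full one
  expect_equal(cWW(13.2, 78.4, 11.5, n = 500, q = 0.5),
               0.25 * cWW(13.2, 78.4, 11.5, n = 500), tolerance = 1e-9)
  # sanity window from independent literature estimates at comparable cutoffs
  cww <- cWW(13.2, 78.4, 11.5)
  expect_gt(cww, 3.3)
  expect_lt(cww, 7.32)
})

test_that("C_LR + C_WW is practically independent of pressure across the dielectric span", {
  ref <- referenceConstants()
  c1 <- vapply(range(ref$epsR), function(e)
    cLR(1, 11.5, 1.7, e) + cWW(13.2, e, 11.5), numeric(1))
  expect_lt(abs(diff(c1)), 0.01)
})

test_that("discrete windowed charging matches the continuous correction and scales as q^2", {
  disc <- cWWDiscrete(q = 1, dq = 0.05, rLR = 13.2, epsR = 78.4,
                      waterCutoff = 11.5, n = 500)
  cont <- cWW(13.2, 78.4, 11.5, n = 500)
  expect_equal(disc$total, cont, tolerance = 0.01)
  expect_equal(nrow(disc$partial), 20)
  # partial sums grow quadratically in the coupled charge
  half <- disc$partial$correction[disc$partial$charge == 0.5]
  expect_equal(half, cont * 0.25, tolerance = 1e-9)
  expect_identical(cWWDiscrete(q = 0, dq = 0.05, rLR = 13.2, epsR = 78.4,
                               waterCutoff = 11.5, n = 100)$total, 0)
})

test_that("C_BA: 1-atm boundary condition, proportionality to density, zero residual", {
  expect_equal(cBA(-7.8, 1), 7.8)          # C_BA(1 atm) = -deltaDg3(1 atm)
  expect_equal(cBA(-7.8, 2), 2 * cBA(-7.8, 1))
  expect_identical(cBA(0, 1.7), 0)
})

test_that("correction ledger identities hold exactly", {
  led <- correctionLedger(cLR = -12.42, cWW = 5.03, cBA = 7.8, Aq = -11.1)
  expect_identical(led$C1, led$cLR + led$cWW)
  expect_identical(led$C2, led$C1 + led$cBA)
  expect_identical(led$C3, led$C1 - led$Aq)
})

test_that("interaction-matrix cutoff mask is symmetric with an untouched diagonal", {
  cav <- tessellateSphere(200, 10)
  Tm <- buildT(cav, 78.4, cutoff = 8)
  expect_true(isSymmetric(Tm$mask))
  expect_false(any(diag(Tm$mask)))
  expect_true(any(Tm$mask))
  expect_true(all(Tm$T[Tm$mask] == 0))
  expect_error(buildT(cav, 78.4, cutoff = -1), "cutoff")
})
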