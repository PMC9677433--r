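# ionhyd

Ion hydration free energies under pressure by Monte Carlo free energy
perturbation, with continuum corrections for potential truncation.

## The problem

The chemical potential μ\* of a monoatomic ion in water — the Ben-Naim
hydration free energy, the work of moving the ion from a fixed position in
ideal gas to a fixed position in solution at infinite dilution — controls
electrolyte thermodynamics in chemistry, geochemistry and biology.  Classical
simulations estimate it for one ion fixed at the center of a periodic box of
rigid four-site (TIP4P) waters, decomposed into a hydrophobic and a
hydrophilic leg:

    μ* = ΔG(0 → LJ) + ΔG(LJ → LJ + q)

each leg computed by free energy perturbation (FEP): the Zwanzig average
ΔG = −kT ln⟨exp(−βΔE)⟩₀ over double-wide λ-windows that scale the ion's
Lennard-Jones parameters and charge linearly.

Sharp molecule-based truncation of the ion–water and water–water Coulomb
interactions at a cutoff R (11.5 Å in production) biases the charging leg.
The package computes the corrections within a continuum dielectric model:

* **C_LR** — the Born energy of the dielectric beyond the cavity radius
  R_LR = R_IW + δ:  C_LR = −(k_C q²/2R_LR)(1 − 1/ε_r);
* **C_WW** — the water–water truncation correction: the cavity surface is
  tessellated into n point charges, the apparent-surface-charge (ASC)
  Poisson solver computes the charging free energy ΔG_q with the full
  surface-charge interaction matrix **T** and with its off-diagonal entries
  zeroed beyond the cutoff; C_WW = ΔG_q − ΔG_q^cut > 0;
* **C_BA** — an empirical boundary-artifact correction proportional to the
  water number density, anchored so the corrected 1-atm value matches the
  experimental reference;
* **−Aq** — a static-potential correction, with A the linear coefficient of
  the quadratic charge-scaling fit ΔG(λq) = A·λq + B·(λq)².

The analysis layer assembles these into correction ledgers
(C₁ = C_LR + C_WW, C₂ = C₁ + C_BA, C₃ = C₁ − Aq), discrepancy tables
against the experimental (Marcus-scale) hydration free energies, ion
differences, electrolyte sums and pressure profiles from 1 to 8000 atm.

## Worked example

Continuum corrections at 1 atm (ε_r = 78.4, production cavity 13.2 Å,
1000 surface points, 11.5 Å cutoff) and the 1-atm discrepancy ledger:

```r
library(ionhyd)

cLR(q = 1, rIW = 11.5, delta = 1.7, epsR = 78.4)
#> [1] -12.4176
cWW(rLR = 13.2, epsR = 78.4, waterCutoff = 11.5, n = 1000)
#> [1] 5.001646

fep <- fepReferenceTable()          # cluster-scale FEP results (inputs)
ref <- referenceConstants()         # experimental references (inputs)
at1 <- subset(fep, P == 1)
corr <- correctionLedger(cLR(1, 11.5, 1.7, 78.4), cWW(13.2, 78.4, 11.5))
led <- discrepancyLedger(setNames(at1$mu, at1$ion), ref, corr,
                         charges = c("K+" = 1, "Rb+" = 1, "Cs+" = 1,
                                     "Br-" = -1, "I-" = -1))
led$printed
#>   ion dGhydExp dDG1  dDG2 dDG3 dDG3minusAq dDG3minusPhiQ
#> 1  K+    -70.5 -0.4 -12.8 -7.8         3.3           6.7
#> 2 Rb+    -65.7 -0.5 -12.9 -7.9         4.1           6.6
#> 3 Cs+    -59.8 -0.5 -12.9 -7.9         5.8           6.6
#> 4 Br-    -75.3 18.0   5.6 10.6        -3.1          -3.9
#> 5  I-    -65.7 17.4   5.0 10.0        -5.3          -4.5
```

Read the ledger as follows: the raw FEP chemical potentials agree with
experiment to a few tenths of a kcal/mol for the cations but are 17–18
kcal/mol too positive for the anions (`dDG1`).  Adding the long-range Born
term alone over-corrects the cations (`dDG2`); adding the water–water
truncation correction brings both within ±8–11 kcal/mol with the
characteristic cation/anion asymmetry (`dDG3`), which the static-potential
column (`dDG3minusAq`) largely removes.

A desk-scale charging leg through the compiled NPT engine (64 waters,
10 double-wide windows; seconds, not the 300 M-trial production runs):

```r
cfg <- generateWaterBox(64, seed = 64, model = loadForcefield()$water,
                        ion = loadForcefield()$ions[["K+"]])
leg <- runLeg(windowSchedule("charge"), cfg, loadForcefield()$ions[["K+"]],
              loadForcefield()$water, cutoffScheme(5.5, 5.5), thermoState(),
              moveSettings(maxVol = 60), nEquil = 1e4, nAvg = 1e5,
              blockSize = 2e4, stride = 20L)
leg$dg   # negative: charging a cation in water is favourable
```

A thin CLI mirrors the package surface
(`inst/cli/ionhyd <corrections|simulate|fep|tau|fit|report|fixtures>`).

## Acceptance script

`scripts/acceptance.R` recomputes the deterministic continuum-correction
surfaces from scratch with the installed package — the closed-form C_LR at
the production cavity and the ASC-solver C_WW at both published
cavity/cutoff combinations — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
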