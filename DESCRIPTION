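Package: ionhyd
Title: Ion Hydration Free Energies Under Pressure by Monte Carlo Free
    Energy Perturbation with Truncation Corrections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the chemical potential (Ben-Naim hydration free
    energy) of monoatomic alkali metal and halide ions in water at
    ambient temperature and elevated pressure.  Provides an NPT
    Metropolis Monte Carlo engine for a fixed ion in rigid four-site
    water with sharp molecule-based potential truncation, free energy
    perturbation with double-wide lambda windows and block statistics,
    and continuum-electrostatics corrections for the truncation of the
    molecular potential: the Born long-range term, a water-water
    truncation correction from an apparent-surface-charge Poisson
    solver with a cutoff in the surface-charge interaction matrix, a
    density-scaled boundary-artifact correction, and a static-potential
    correction from quadratic charge-scaling fits.  An analysis layer
    assembles correction ledgers, ion differences, electrolyte sums and
    pressure profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
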