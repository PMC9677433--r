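{
  "comment": "Rigid four-site water model (TIP4P) and monovalent ion Lennard-Jones parameters from the standard OPLS-compatible alkali/halide parameter set. Units: Angstrom, kcal/mol, elementary charge. Geometric-mean combining for both sigma and epsilon.",
  "water": {
    "name": "TIP4P",
    "rOH": 0.9572,
    "thetaHOH": 104.52,
    "rOM": 0.15,
    "qH": 0.52,
    "qM": -1.04,
    "sigmaO": 3.15365,
    "epsO": 0.155,
    "numberDensity1atm": 0.03333
  },
  "ions": {
    "K+":  { "charge":  1, "sigma": 5.17, "eps": 0.0005 },
    "Rb+": { "charge":  1, "sigma": 5.60, "eps": 0.0005 },
    "Cs+": { "charge":  1, "sigma": 6.20, "eps": 0.0005 },
    "Br-": { "charge": -1, "sigma": 4.28, "eps": 0.71 },
    "I-":  { "charge": -1, "sigma": 4.81, "eps": 0.71 }
  }
}
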