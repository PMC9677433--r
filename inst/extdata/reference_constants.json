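{
  "comment": "Reference constants for the analysis layer.  These are inputs, never computed.  dGhydExp: experimental single-ion hydration free energies (kcal/mol) on the Marcus conventional absolute scale (ideal gas 1 mol/L -> ideal solution 1 mol/L).  phi: air/water interface potential of the TIP4P model, kcal/(mol e).  A1atm: static electrostatic potential at the solute site from quadratic charge-scaling fits of the cluster-scale charging curves over lambda in [0.2, 0.5] at 1 atm, kcal/(mol e).  epsR: experimental static dielectric constant of water at 298.15 K versus pressure (atm).  rhoRatio: TIP4P water number density relative to 1 atm at the same pressures.",
  "dGhydExp": { "K+": -70.5, "Rb+": -65.7, "Cs+": -59.8, "Br-": -75.3, "I-": -65.7 },
  "phi": -14.53,
  "A1atm": { "K+": -11.1, "Rb+": -12.0, "Cs+": -13.7, "Br-": -13.7, "I-": -15.3 },
  "pressures": [1, 1000, 2000, 3000, 4000, 6000, 8000],
  "epsR": [78.4, 82.0, 85.4, 88.5, 91.4, 96.9, 102.0],
  "rhoRatio": [1.000, 1.044, 1.077, 1.105, 1.128, 1.169, 1.203]
}
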