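{
  "version": "IUPAC-2021-representative",
  "source": "IUPAC CIAAW representative terrestrial isotopic compositions (2021)",
  "comment": "Mass shifts are integer nominal-mass offsets from the lightest (monoisotopic) isotope. Probabilities per element sum to 1.",
  "elements": {
    "H":  { "shifts": [0, 1],       "abundances": [0.999885, 0.000115] },
    "C":  { "shifts": [0, 1],       "abundances": [0.9893, 0.0107] },
    "N":  { "shifts": [0, 1],       "abundances": [0.99636, 0.00364] },
    "O":  { "shifts": [0, 1, 2],    "abundances": [0.99757, 0.00038, 0.00205] },
    "Si": { "shifts": [0, 1, 2],    "abundances": [0.92223, 0.04685, 0.03092] },
    "S":  { "shifts": [0, 1, 2, 4], "abundances": [0.9499, 0.0075, 0.0425, 0.0001] },
    "P":  { "shifts": [0],          "abundances": [1.0] },
    "F":  { "shifts": [0],          "abundances": [1.0] },
    "Na": { "shifts": [0],          "abundances": [1.0] },
    "Cl": { "shifts": [0, 2],       "abundances": [0.7576, 0.2424] },
    "K":  { "shifts": [0, 1, 2],    "abundances": [0.932581, 0.000117, 0.067302] }
  }
}
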