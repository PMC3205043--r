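# Single-bond covalent radii (same length unit as atom coordinates) and the
# distance tolerance used for bond perception: two atoms are bonded when
# their separation is at most r1 + r2 + tolerance.
tolerance: 0.40
# (symbols quoted: bare N/F/Y would be read as YAML booleans)
radii:
  "H": 0.37
  "B": 0.82
  "C": 0.77
  "N": 0.75
  "O": 0.73
  "F": 0.71
  "Si": 1.11
  "P": 1.06
  "S": 1.02
  "Cl": 0.99
  "Br": 1.14
  "I": 1.33
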