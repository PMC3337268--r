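# Default harmonization map bridging the two carcinogenicity call
# encodings: CPDBAS-style ActivityOutcome strings and ISSCAN-style numeric
# Canc codes (3 = carcinogen, 2 = equivocal, 1 = non-carcinogen).
ActivityOutcome:
  active: POSITIVE
  unspecified: EQUIVOCAL
  inactive: NEGATIVE
Canc:
  "3": POSITIVE
  "2": EQUIVOCAL
  "1": NEGATIVE
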