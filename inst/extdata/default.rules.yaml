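# Default conversion ruleset: the expert rule instances the toolchain
# encodes out of the box.
containers:
  - Tests
  - Compounds
renames:
  Study/TreatmentGroup/Results: TreatmentResults
promotions: []
subclasses:
  - [ChronicStudies, Study]
unify: {}
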