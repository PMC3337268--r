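cpdbas-001
  toxowl

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <ActivityOutcome>
active

> <CASRN>
50-00-0

$$$$
cpdbas-002
  toxowl

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <ActivityOutcome>
active

> <CASRN>
62-53-3

$$$$
cpdbas-003
  toxowl

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <ActivityOutcome>
inactive

> <CASRN>
64-17-5

$$$$
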