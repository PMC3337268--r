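isscan-001
  toxowl

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <Canc>
3

> <CASRN>
107-13-1

$$$$
isscan-002
  toxowl

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
M  END
> <Canc>
1

> <CASRN>
57-55-6

$$$$
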