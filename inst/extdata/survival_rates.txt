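0/5 (weeks 27-30)
10/10
16/17
5/5
6/6
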