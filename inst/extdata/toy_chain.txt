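# two-reaction toy network (non-unit coefficients)
r1: 1.0 c1 + 2.0 c2 -> 1.0 c3
r2: 3.0 c3 -> 1.0 c4
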