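cell	w1	w2	w3	w4
c1	25	25	25	25
c2	25	25	25	0
c3	25	25	0	0
c4	0	0	0	0
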