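S1	toy set one	G1	G2
S2	toy set two	G2	G3
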