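group	negative	low	high
pT2	3965	5303	287
pT3a	1165	2033	168
pT3b_pT4	609	1279	142
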