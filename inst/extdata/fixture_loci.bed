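7	1000000	1400000	EXOC4
1	2000000	2100000	1q23.1
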