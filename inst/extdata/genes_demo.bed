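chr1	10000	12000	DEMO_A	0	+
chr1	200000	205000	DEMO_B	0	-
chr1	400000	450000	DEMO_C	0	+
chr1	700000	820000	DEMO_D	0	+
chr1	460000	510000	DEMO_E	0	-
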