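chrom	start	end	strand	gene_id
chr1	0	30000	+	EXP_G1
chr1	40000	70000	+	EXP_G2
chr1	100000	130000	+	EXP_G3
chr1	105000	135000	+	EXP_G4
chr1	200000	220000	+	EXP_G5
chr1	300000	330000	+	EXP_G6
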