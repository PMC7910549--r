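condition	timepoint	fraction
TIR1	mock	1.0
TIR1	3h	0.50
TIR1	8h	0.72
TIR1	24h	0.95
PAF1_AID	mock	1.0
PAF1_AID	3h	0.62
PAF1_AID	8h	0.55
PAF1_AID	24h	0.60
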