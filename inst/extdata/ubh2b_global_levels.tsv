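condition	fraction
WT_mock	1.0
WT_9J8h	0.63
CSB_KO_mock	1.0
CSB_KO_9J8h	0.38
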