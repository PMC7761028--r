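seq	W-box	G-box	GCC-box	TCA-element	MeJa-RE	ERE
AaGSW1_Aa_PWA39112	10	1	2	0	4	0
AaWRKY1_Aa_PWA52969	8	1	0	0	4	2
AA2132240_Aa_PWA78774	7	0	1	0	3	0
Aa_PWA73483	5	1	1	0	5	2
Aa_PWA66309	5	1	1	0	7	2
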