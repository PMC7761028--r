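seq	W-box	G-box	GCC-box	TCA-element	MeJa-RE	ERE
Aa_PWA66309	5	1	1	0	7	2
Aa_WRKY40	5	1	1	0	5	2
At_WRKY18	6	0	1	0	5	0
At_WRKY40	5	0	0	0	5	1
B456_001G037700	6	1	0	0	5	8
Ccrd_002370	6	1	0	0	5	2
Lsat_1_v5_gn_3_25221	7	0	0	0	5	0
Aa_PWA93143	4	0	0	0	4	1
B456_001G037800	7	1	1	0	4	1
Ha_OTF90414	4	0	0	0	4	3
Lsat_1_v5_gn_5_62060	6	0	0	0	4	2
Aa_PWA52888	4	0	0	0	3	1
Aa_PWA75822	3	0	0	0	3	2
B456_009G062400	9	0	0	0	3	1
Ccrd_006339	4	0	0	0	3	3
Ha_OTF85347	4	0	0	0	3	7
Ha_OTG16715	6	0	0	0	3	1
Ha_OTG32071	2	0	3	0	3	4
Ha_OTG33233	4	2	0	0	3	3
Aa_PWA17905	6	0	0	0	2	0
Lsat_1_v5_gn_4_86881	10	1	0	0	2	4
Aa_PWA79841	7	0	0	0	1	1
At_WRKY60	8	0	0	0	1	1
B456_009G062300	6	1	0	0	1	4
B456_010G118300	6	0	0	0	1	10
B456_010G222400	6	0	0	1	1	3
Ccrd_006337	2	0	0	0	1	2
Ccrd_006338	2	0	0	0	1	2
Aa_PWA42409	3	0	0	0	0	0
B456_009G124000	7	0	0	0	0	8
Ccrd_015573	6	1	0	0	0	2
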