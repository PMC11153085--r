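salt_pct	sample_id	sample_type	bacteria_cfu	bacteria_sd	yeast_cfu	yeast_sd
0	0a	fly	895000	161142	3480	972
0	0b	fly	2860000	245085	560	246
0	0c	fly	7585000	2741660	0	0
0	s0b	substrate	97700000	8808140	20	63
0	s0c	substrate	13021000	1606238	1020	670
2	2a	fly	47200	11013	96740	10688
2	2b	fly	9900	2094	191160	60733
2	2c	fly	20100	2051	295300	83388
2	s2a	substrate	151400	52244	118960	20188
4	4a	fly	2107500	229982	133400	32146
4	4b	fly	21840000	2633755	139120	41235
4	4c	fly	6005000	599138	504440	149799
4	s4a	substrate	4492500	803632	201240	59948
7	7a	fly	8295300	957967	52306	12370
7	7b	fly	1390400	422926	2068	1029
7	s7a	substrate	3100	354	29596	11460
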