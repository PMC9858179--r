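order	cas	iupac	direction	ethylene
1	000554-12-1	Methyl propanoate	1	1
2	000108-21-4	1-Methylethyl acetate	1	1
3	001534-08-3	S-Methyl ethanethioate	1	-1
5	000623-42-7	Methyl butanoate	1	1
6	000137-32-6	2-Methylbutan-1-ol	1	1
7	000110-19-0	2-Methylpropyl acetate	1	1
8	000868-57-5	Methyl 2-methylbutanoate	1	-1
10	000106-36-5	Propyl propanoate	1	1
11	000123-86-4	Butyl acetate	1	1
12	002432-51-1	1-Methylsulfanylbutan-1-one	1	1
13	000123-92-2	3-Methylbutyl acetate	1	1
14	000624-41-9	2-Methylbutyl acetate	1	-1
15	000100-42-5	Ethenylbenzene	-1	1
16	016630-66-3	Methyl 2-methylsulfanylacetate	1	1
17	001191-16-8	3-Methylbut-2-enyl acetate	1	-1
18	023747-45-7	3-Methyl-1-methylsulfanyl-butan-1-one	1	1
20	115051-66-6	1-(3-Hydroxypropylsulfanyl)ethanone	1	1
21	000142-92-7	Hexyl acetate	1	-1
22	000470-82-6	1,8,8-Trimethyl-7-oxabicyclo[2-2-2]octane	1	1
24	NID1	NID1 (LRI 1143; RT 20.871)	1	1
26	000140-11-4	Benzyl acetate	1	1
30	000103-45-7	2-Phenylethyl acetate	1	-1
31	074367-33-2	(1-Hydroxy-2,4,4-trimethyl-pentan-3-yl) 2-methylpropanoate	-1	-1
39	000079-77-6	(E)-4-(2,6,6-Trimethyl-1-cyclohexenyl)but-3-en-2-one	1	-1
41	000074-93-1	Methanethiol	-1	-1
46	000123-72-8	Butanal	-1	-1
49	000123-73-9	But-2-enal	-1	-1
54	017528-72-2	Pent-1-en-3-one	-1	-1
57	000108-10-1	4-Methylpentan-2-one	-1	1
58	068920-64-9	Methyldisulfanylmethane	-1	-1
60	NID4	NID4 (LRI 734; RT 3.229)	1	-1
61	000105-46-4	Butan-2-yl acetate	1	1
63	000820-71-3	2-Methylprop-2-enyl acetate	1	1
64	000066-25-1	Hexanal	-1	-1
69	000816-11-5	Methyl 2-ethylbutanoate	1	-1
70	000540-42-1	2-Methylpropyl propanoate	1	1
72	000628-63-7	Pentyl acetate	1	1
73	000591-23-1	3-Methylcyclohexan-1-ol	-1	-1
76	000108-83-8	2,6-Dimethylheptan-4-one	-1	-1
80	001193-81-3	(2-Methylcyclohexyl)methanol	-1	-1
81	001114-92-7 (meso)	3-Acetyloxybutan-2-yl acetate, meso	1	-1
83	001114-92-7 (rac)	3-Acetyloxybutan-2-yl acetate, rac	1	-1
89	000112-06-1	Heptyl acetate	1	-1
110	74367-31-0	2-Ethyl-3-hydroxyhexyl 2-methylpropanoate	-1	-1
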