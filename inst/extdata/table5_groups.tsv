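group	order	cas	iupac
G1	33	000079-20-9	Methyl acetate
G1	35	000078-83-1	2-Methylpropan-1-ol
G1	1	000554-12-1	Methyl propanoate
G1	3	001534-08-3	S-Methyl ethanethioate
G1	4	000109-60-4	Propyl acetate
G1	5	000623-42-7	Methyl butanoate
G1	6	000137-32-6	2-Methylbutan-1-ol
G1	7	000110-19-0	2-Methylpropyl acetate
G1	8	000868-57-5	Methyl 2-methylbutanoate
G1	63	000820-71-3	2-Methylprop-2-enyl acetate
G1	10	000106-36-5	Propyl propanoate
G1	11	000123-86-4	Butyl acetate
G1	12	002432-51-1	1-Methylsulfanylbutan-1-one
G1	66	005271-38-5	2-Methylsulfanylethanol
G1	70	000540-42-1	2-Methylpropyl propanoate
G1	13	000123-92-2	3-Methylbutyl acetate
G1	14	000624-41-9	2-Methylbutyl acetate
G1	72	000628-63-7	Pentyl acetate
G1	16	016630-66-3	Methyl 2-methylsulfanylacetate
G1	17	001191-16-8	3-Methylbut-2-enyl acetate
G1	18	023747-45-7	3-Methyl-1-methylsulfanyl-butan-1-one
G1	20	115051-66-6	1-(3-Hydroxypropylsulfanyl)ethanone
G1	21	000142-92-7	Hexyl acetate
G1	22	000470-82-6	1,8,8-Trimethyl-7-oxabicyclo[2-2-2]octane
G1	24	NID1	NID1 (LRI 1143; RT 20.871)
G1	26	000140-11-4	Benzyl acetate
G1	28	007371-86-0	4-Acetyloxypentan-2-yl acetate
G1	30	000103-45-7	2-Phenylethyl acetate
G2	46	000123-72-8	Butanal
G2	49	000123-73-9	But-2-enal
G2	53	000616-25-1	Pent-1-en-3-ol
G2	54	017528-72-2	Pent-1-en-3-one
G2	59	000565-69-5	2-Methylpentan-3-one
G2	64	000066-25-1	Hexanal
G3	51	068411-77-8	Cyclohexane
G3	36	000108-88-3	Methylbenzene
G3	67	018729-48-1	3-Methylcyclopentan-1-ol
G3	9	000105-54-4	Ethyl butanoate
G4	65	NID2	NID2 (LRI 908; RT 8.645)
G4	85	001565-75-9	2-Phenylbutan-2-ol
G4	98	002040-07-5	1-(2,4,5-Trimethylphenyl)ethanone
G5	15	000100-42-5	Ethenylbenzene
G5	73	000591-23-1	3-Methylcyclohexan-1-ol
G5	77	005441-52-1	3,5-Dimethylcyclohexan-1-ol
G5	80	001193-81-3	(2-Methylcyclohexyl)methanol
G5	92	000464-49-3	1,7,7-Trimethylbicyclo[2.2.1]heptan-2-one
G5	31	074367-33-2	(1-Hydroxy-2,4,4-trimethyl-pentan-3-yl) 2-methylpropanoate
G5	110	74367-31-0	2-Ethyl-3-hydroxyhexyl 2-methylpropanoate
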