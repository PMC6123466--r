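Hugo_Symbol	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification	Variant_Type	Tumor_Sample_Barcode	t_ref_count	t_alt_count	Protein_Change
PIK3CA	1	1003138	A	G	Missense_Mutation	SNP	S0003	119	33	S1047H
PIK3CA	1	1003138	A	G	Missense_Mutation	SNP	S0004	92	45	S1047H
PIK3CA	1	1001813	T	C	Missense_Mutation	SNP	S0007	79	30	A605I
PIK3CA	1	1002019	T	A	Missense_Mutation	SNP	S0008	135	56	W674V
PIK3CA	1	1003138	A	C	Missense_Mutation	SNP	S0011	103	42	S1047H
PIK3CA	1	1003138	T	A	Missense_Mutation	SNP	S0012	126	40	S1047H
TP53	2	2000061	T	G	Missense_Mutation	SNP	S0004	103	51	H21R
TP53	2	2001030	A	G	Missense_Mutation	SNP	S0008	135	55	H344G
TP53	2	2000158	T	A	Nonsense_Mutation	SNP	S0010	97	49	L53S
TP53	2	2000441	A	AT	Frame_Shift_Ins	INS	S0012	90	31	H148Y
MAP3K1	3	3002122	T	C	Splice_Region	SNP	S0009	107	46	I708G
MAP3K1	3	3001170	AT	A	Frame_Shift_Del	DEL	S0011	104	31	G391D
MAP3K1	3	3001702	T	C	Nonsense_Mutation	SNP	S0012	104	37	G568D
PIK3CA	1	1000935	C	G	Missense_Mutation	SNP	S0002	44	55	T312T
PIK3CA	1	1000365	G	A	Missense_Mutation	SNP	S0003	38	27	T122K
MAP3K1	3	3001051	T	C	Frame_Shift_Del	SNP	S0004	75	66	R351E
PIK3CA	1	1000147	A	G	Missense_Mutation	SNP	S0005	65	65	G50Y
TP53	2	2000334	G	T	Missense_Mutation	SNP	S0006	100	101	S112N
TP53	2	2000454	T	G	Missense_Mutation	SNP	S0008	54	40	R152A
PIK3CA	1	1001609	T	C	Nonsense_Mutation	SNP	S0008	43	68	E537Y
PIK3CA	1	1000719	C	T	Missense_Mutation	SNP	S0008	70	47	I240D
TP53	2	2000498	T	C	Missense_Mutation	SNP	S0008	76	56	H167G
PIK3CA	1	1003123	A	C	Missense_Mutation	SNP	S0009	33	28	V1042E
MAP3K1	3	3002382	T	A	Nonsense_Mutation	SNP	S0011	75	107	N795E
TP53	2	2000964	A	C	Nonsense_Mutation	SNP	S0012	83	69	Y322W
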