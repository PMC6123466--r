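chrom	pos	ref	alt	var_reads	depth
1	1000935	C	G	59	112
1	1000935	C	G	76	131
1	1000935	C	G	40	74
1	1000935	C	G	160	312
1	1000935	C	G	58	112
1	1000365	G	A	89	159
1	1000365	G	A	58	109
1	1000365	G	A	37	82
1	1000365	G	A	21	52
1	1000365	G	A	57	120
1	1000365	G	A	152	319
1	1000365	G	A	46	100
1	1000365	G	A	56	99
1	1000365	G	A	66	122
1	1000365	G	A	68	141
1	1000365	G	A	126	242
3	3001051	T	C	106	208
3	3001051	T	C	72	149
3	3001051	T	C	65	118
3	3001051	T	C	81	151
3	3001051	T	C	44	88
3	3001051	T	C	40	77
3	3001051	T	C	80	186
3	3001051	T	C	66	118
3	3001051	T	C	103	210
3	3001051	T	C	58	119
3	3001051	T	C	121	244
3	3001051	T	C	23	50
3	3001051	T	C	70	154
3	3001051	T	C	108	206
3	3001051	T	C	108	218
3	3001051	T	C	139	263
1	1000147	A	G	109	256
1	1000147	A	G	84	171
1	1000147	A	G	28	54
1	1000147	A	G	99	198
1	1000147	A	G	47	95
1	1000147	A	G	73	154
1	1000147	A	G	66	131
1	1000147	A	G	81	184
1	1000147	A	G	91	180
1	1000147	A	G	80	164
1	1000147	A	G	85	155
2	2000334	G	T	32	75
2	2000334	G	T	107	210
2	2000334	G	T	72	143
2	2000334	G	T	35	78
2	2000334	G	T	32	59
2	2000334	G	T	72	160
2	2000334	G	T	124	239
2	2000334	G	T	84	161
2	2000334	G	T	89	191
2	2000334	G	T	71	127
2	2000334	G	T	75	149
2	2000334	G	T	43	74
2	2000334	G	T	66	151
2	2000334	G	T	64	119
2	2000334	G	T	42	80
2	2000334	G	T	43	79
2	2000334	G	T	63	124
2	2000334	G	T	66	118
2	2000334	G	T	35	72
2	2000334	G	T	82	159
2	2000334	G	T	89	186
2	2000334	G	T	44	107
2	2000334	G	T	52	101
2	2000454	T	G	47	90
2	2000454	T	G	102	185
2	2000454	T	G	102	218
2	2000454	T	G	93	200
2	2000454	T	G	66	117
2	2000454	T	G	15	33
2	2000454	T	G	59	133
2	2000454	T	G	95	180
2	2000454	T	G	90	164
2	2000454	T	G	58	112
2	2000454	T	G	32	73
2	2000454	T	G	67	112
2	2000454	T	G	17	47
2	2000454	T	G	53	112
2	2000454	T	G	31	65
2	2000454	T	G	58	102
2	2000454	T	G	54	97
1	1001609	T	C	134	260
1	1001609	T	C	47	108
1	1001609	T	C	76	143
1	1001609	T	C	51	119
1	1001609	T	C	51	108
1	1000719	C	T	133	241
1	1000719	C	T	60	117
1	1000719	C	T	52	107
1	1000719	C	T	57	122
1	1000719	C	T	77	156
1	1000719	C	T	81	152
1	1000719	C	T	61	121
1	1000719	C	T	62	137
1	1000719	C	T	31	75
1	1000719	C	T	73	147
1	1000719	C	T	47	84
1	1000719	C	T	94	167
1	1000719	C	T	47	112
1	1000719	C	T	57	111
1	1000719	C	T	65	133
1	1000719	C	T	39	82
1	1000719	C	T	56	106
1	1000719	C	T	50	104
1	1000719	C	T	61	103
1	1000719	C	T	83	155
1	1000719	C	T	87	179
1	1000719	C	T	77	145
1	1000719	C	T	41	83
1	1000719	C	T	54	102
2	2000498	T	C	40	71
2	2000498	T	C	71	131
2	2000498	T	C	54	92
2	2000498	T	C	84	160
2	2000498	T	C	31	70
2	2000498	T	C	43	95
2	2000498	T	C	160	294
2	2000498	T	C	46	91
2	2000498	T	C	68	147
2	2000498	T	C	82	146
2	2000498	T	C	69	142
2	2000498	T	C	49	111
1	1003123	A	C	86	178
1	1003123	A	C	78	144
1	1003123	A	C	65	130
1	1003123	A	C	43	109
1	1003123	A	C	33	69
1	1003123	A	C	56	119
1	1003123	A	C	64	108
1	1003123	A	C	72	138
1	1003123	A	C	87	180
1	1003123	A	C	77	149
3	3002382	T	A	65	120
3	3002382	T	A	50	103
3	3002382	T	A	70	149
3	3002382	T	A	73	131
3	3002382	T	A	74	149
3	3002382	T	A	79	159
3	3002382	T	A	45	104
3	3002382	T	A	53	126
3	3002382	T	A	51	85
3	3002382	T	A	90	172
3	3002382	T	A	54	130
3	3002382	T	A	71	137
3	3002382	T	A	78	160
2	2000964	A	C	77	171
2	2000964	A	C	111	202
2	2000964	A	C	91	176
2	2000964	A	C	139	274
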