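chrom	pos	ref	alt	n_called
1	1000935	C	G	3
1	1000365	G	A	11
3	3001051	T	C	19
1	1000147	A	G	23
2	2000334	G	T	44
2	2000454	T	G	27
1	1001609	T	C	11
1	1000719	C	T	48
2	2000498	T	C	17
1	1003123	A	C	20
3	3002382	T	A	29
2	2000964	A	C	6
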