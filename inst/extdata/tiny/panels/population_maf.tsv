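chrom	pos	ref	alt	maf_1kg	maf_nhlbi	maf_exac
1	1000935	C	G	0.0214940713631795	0.0214940713631795	0.0214940713631795
1	1000365	G	A	0.0564100754070958	0.0564100754070958	0.0564100754070958
3	3001051	T	C	0.0885096644957289	0.0885096644957289	0.0885096644957289
1	1000147	A	G	0.0908364298387626	0.0908364298387626	0.0908364298387626
2	2000334	G	T	0.1302797224147453	0.1302797224147453	0.1302797224147453
2	2000454	T	G	0.1008094144485013	0.1008094144485013	0.1008094144485013
1	1001609	T	C	0.0212264484531820	0.0212264484531820	0.0212264484531820
1	1000719	C	T	0.1810736165499015	0.1810736165499015	0.1810736165499015
2	2000498	T	C	0.0615971782264419	0.0615971782264419	0.0615971782264419
1	1003123	A	C	0.0703351190931484	0.0703351190931484	0.0703351190931484
3	3002382	T	A	0.1153777764384091	0.1153777764384091	0.1153777764384091
2	2000964	A	C	0.0316815436798365	0.0316815436798365	0.0316815436798365
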