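sample_id	endpoint	time	event
S0001	BCSS	11.630698	1
S0002	BCSS	25.000000	0
S0003	BCSS	25.000000	0
S0004	BCSS	7.123757	0
S0005	BCSS	2.163698	1
S0006	BCSS	14.624197	0
S0007	BCSS	25.000000	0
S0008	BCSS	12.337956	0
S0009	BCSS	5.856528	0
S0010	BCSS	13.551120	0
S0011	BCSS	2.536544	0
S0012	BCSS	24.099452	0
S0001	RFS	19.921153	1
S0002	RFS	14.030149	0
S0003	RFS	25.000000	0
S0004	RFS	25.000000	0
S0005	RFS	9.832289	0
S0006	RFS	22.579556	0
S0007	RFS	2.363603	1
S0008	RFS	7.356695	0
S0009	RFS	7.261604	1
S0010	RFS	15.073119	1
S0011	RFS	25.000000	0
S0012	RFS	25.000000	0
S0001	OS	3.380609	1
S0002	OS	25.000000	0
S0003	OS	17.160214	1
S0004	OS	19.022995	1
S0005	OS	11.487911	1
S0006	OS	20.624800	0
S0007	OS	25.000000	0
S0008	OS	1.934871	1
S0009	OS	25.000000	0
S0010	OS	11.035195	1
S0011	OS	6.493284	1
S0012	OS	17.896012	1
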