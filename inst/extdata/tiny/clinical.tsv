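sample_id	age	grade	nodes_positive	tumor_size_category	er_status	pr_status	her2_status	her2_amplified	subtype
S0001	85	2	2	2	positive	unknown	negative	FALSE	LumA
S0002	81	3	0	4	positive	unknown	negative	FALSE	LumA
S0003	66	2	2	2	positive	unknown	negative	FALSE	LumB
S0004	53	2	0	1	positive	unknown	negative	FALSE	LumA
S0005	58	3	2	2	positive	unknown	negative	FALSE	LumB
S0006	61	3	1	3	positive	unknown	negative	FALSE	LumB
S0007	75	3	0	3	positive	unknown	negative	FALSE	LumB
S0008	65	3	2	3	positive	unknown	negative	FALSE	LumB
S0009	30	2	0	1	positive	unknown	negative	FALSE	LumA
S0010	78	1	2	2	positive	unknown	positive	TRUE	HER2E
S0011	70	2	3	3	positive	unknown	negative	FALSE	LumA
S0012	86	2	0	3	positive	unknown	negative	FALSE	LumA
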