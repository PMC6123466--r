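sample_id	frac_bases_gt20
S0001	0.8793
S0002	0.9781
S0003	0.9264
S0004	0.9471
S0005	0.9384
S0006	0.9816
S0007	0.9226
S0008	0.9616
S0009	0.9410
S0010	0.9278
S0011	0.9615
S0012	0.9377
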