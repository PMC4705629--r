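gene_id	ratio	z_score	p_one_sided	bh_threshold	significant
PLCH2	0.490	-3.359	0.00039	0.00109	TRUE
KIAA1919	0.492	-3.342	0.00041	0.00217	TRUE
MRPS34	0.528	-3.030	0.00122	0.00326	TRUE
EPPK1	0.607	-2.365	0.00901	0.00435	FALSE
NAT10	0.612	-2.281	0.01127	0.00544	FALSE
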