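gene_id	ratio	z_score	p_one_sided	bh_threshold	significant
TACC2	0.196	-6.090	0.0000	0.0010	TRUE
MYO1E	0.614	-2.924	0.0017	0.0020	TRUE
NPLOC4	0.727	-2.070	0.0192	0.0030	FALSE
FUT2	0.763	-1.796	0.0363	0.0040	FALSE
PEX26	0.797	-1.537	0.0622	0.0050	FALSE
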