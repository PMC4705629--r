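gene_id	ratio	z_score	p_one_sided	bh_threshold	significant
SLC7A1	1.334	2.959	0.0015	0.0016	TRUE
INO80	1.213	1.882	0.0300	0.0032	FALSE
AXIN1	1.190	1.878	0.0302	0.0048	FALSE
EREG	1.189	1.673	0.0471	0.0065	FALSE
MAP3K10	1.177	1.519	0.0644	0.0081	FALSE
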