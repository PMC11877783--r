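chrom	pos	ref	alt	gene	GBM-260_B.depth	GBM-260_B.alt	GBM-260_SVZ.depth	GBM-260_SVZ.alt	GBM-260_P.depth	GBM-260_P.alt	GBM-260_R.depth	GBM-260_R.alt
chr13	48367512	G	T	RB1	1002	0	1005	0	1005	265	1005	0
chr17	7673802	C	T	TP53	1000	0	1005	0	1005	0	1010	250
chr5	1295228	G	A	TERT	1007	0	1024	33	1016	339	1012	308
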