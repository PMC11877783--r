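chrom	pos	ref	alt	gene	GBM-1938_B.depth	GBM-1938_B.alt	GBM-1938_SVZ.depth	GBM-1938_SVZ.alt	GBM-1938_P.depth	GBM-1938_P.alt	GBM-1938_R.depth	GBM-1938_R.alt
chr10	87952200	G	T	PTEN	1000	0	1019	18	1007	315	1011	280
chr17	7674220	A	G	TP53	1003	0	1005	0	1012	225	1005	0
chr17	7674945	C	T	TP53	1001	0	1005	0	1005	0	1004	240
chr3	179210191	G	A	PIK3CA	1002	0	1005	0	1005	0	1006	205
chr3	179239627	A	T	PIK3CA	1000	0	1005	0	1000	180	980	1
chr4	54274888	C	T	PDGFRA	1002	0	1025	22	1018	330	1005	287
chr5	1295228	G	A	TERT	1006	0	1032	31	1009	348	1013	311
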