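chrom	pos	ref	alt	gene	GBM-1932_B.depth	GBM-1932_B.alt	GBM-1932_SVZ.depth	GBM-1932_SVZ.alt	GBM-1932_P.depth	GBM-1932_P.alt	GBM-1932_R.depth	GBM-1932_R.alt
chr11	534242	A	G	HRAS	1002	498	1010	495	1000	430	1001	470
chr17	29554262	G	A	NF1	1010	0	1005	0	1000	310	995	285
chr5	1295228	G	A	TERT	1000	0	1040	24	1012	352	1021	305
chr7	151860521	T	C	KMT2C	1000	1	1005	0	1005	0	1002	140
chrX	76938112	C	T	ATRX	1005	0	1005	0	1010	150	980	1
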