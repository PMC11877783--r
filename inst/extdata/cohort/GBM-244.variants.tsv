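chrom	pos	ref	alt	gene	GBM-244_B.depth	GBM-244_B.alt	GBM-244_SVZ.depth	GBM-244_SVZ.alt	GBM-244_P.depth	GBM-244_P.alt	GBM-244_R.depth	GBM-244_R.alt
chr1	158612300	T	A	SPTA1	1063	0	1005	0	1063	230	1005	0
chr4	55110500	A	G	KDR	1063	0	1005	0	1005	0	1063	226
chr5	1295228	G	A	TERT	1063	0	1063	27	1063	372	1063	319
chr7	55154129	C	T	EGFR	1063	0	1063	20	1063	335	1063	290
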