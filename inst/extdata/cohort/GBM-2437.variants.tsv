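chrom	pos	ref	alt	gene	GBM-2437_B.depth	GBM-2437_B.alt	GBM-2437_SVZ.depth	GBM-2437_SVZ.alt	GBM-2437_P.depth	GBM-2437_P.alt	GBM-2437_R.depth	GBM-2437_R.alt
chr1	185934622	G	A	HMCN1	1000	0	1005	0	26	0	1005	125
chr19	8943812	C	T	MUC16	1001	0	1005	0	1008	135	26	0
chr5	1295228	G	A	TERT	1009	0	1037	23	1021	347	1015	290
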