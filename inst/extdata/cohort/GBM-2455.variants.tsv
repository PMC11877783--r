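chrom	pos	ref	alt	gene	GBM-2455_B.depth	GBM-2455_B.alt	GBM-2455_SVZ.depth	GBM-2455_SVZ.alt	GBM-2455_P.depth	GBM-2455_P.alt	GBM-2455_R.depth	GBM-2455_R.alt
chr1	228402412	G	T	OBSCN	1003	0	1005	0	26	0	1000	110
chr2	169983882	C	A	LRP2	1000	0	1005	0	1010	120	26	0
chr5	1295228	G	A	TERT	1004	0	1029	25	1014	350	1006	302
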