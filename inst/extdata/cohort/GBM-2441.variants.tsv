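chrom	pos	ref	alt	gene	GBM-2441_B.depth	GBM-2441_B.alt	GBM-2441_SVZ.depth	GBM-2441_SVZ.alt	GBM-2441_P.depth	GBM-2441_P.alt	GBM-2441_R.depth	GBM-2441_R.alt
chr17	29559932	C	A	NF1	1004	0	1005	0	1003	240	1005	0
chr4	54285926	G	A	PDGFRA	1000	0	1005	0	980	1	1008	215
chr5	1295228	G	A	TERT	1001	0	1015	21	1013	344	1002	296
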