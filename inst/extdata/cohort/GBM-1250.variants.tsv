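chrom	pos	ref	alt	gene	GBM-1250_B.depth	GBM-1250_B.alt	GBM-1250_SVZ.depth	GBM-1250_SVZ.alt	GBM-1250_P.depth	GBM-1250_P.alt	GBM-1250_R.depth	GBM-1250_R.alt
chr1	158666421	A	C	SPTA1	1004	0	1005	0	1010	210	1005	0
chr1	158680532	C	T	SPTA1	1008	0	1005	0	1005	0	1000	195
chr10	87925512	A	T	PTEN	1000	0	1005	0	1006	290	1005	0
chr10	87933010	C	G	PTEN	1001	0	1005	0	980	1	1009	270
chr17	7676154	G	C	TP53	1002	498	1015	508	1002	470	1010	455
chr5	1295228	G	A	TERT	1003	0	1018	28	1011	361	1016	320
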