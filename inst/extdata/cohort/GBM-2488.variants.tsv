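chrom	pos	ref	alt	gene	GBM-2488_B.depth	GBM-2488_B.alt	GBM-2488_SVZ.depth	GBM-2488_SVZ.alt	GBM-2488_P.depth	GBM-2488_P.alt	GBM-2488_R.depth	GBM-2488_R.alt
chr10	87864488	CTTTGA	C	PTEN	1005	0	1005	0	1005	0	1002	230
chr10	87961042	TGCAA	T	PTEN	1000	0	1005	0	1014	260	1005	0
chr12	25245350	C	T	KRAS	1002	498	1000	512	1011	489	1007	461
chr5	1295228	G	A	TERT	1010	0	1041	26	1020	356	1018	300
chr7	55191822	G	A	EGFR	1003	0	1005	0	1009	195	1005	0
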