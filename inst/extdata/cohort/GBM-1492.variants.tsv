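chrom	pos	ref	alt	gene	GBM-1492_B.depth	GBM-1492_B.alt	GBM-1492_SVZ.depth	GBM-1492_SVZ.alt	GBM-1492_P.depth	GBM-1492_P.alt	GBM-1492_R.depth	GBM-1492_R.alt
chr13	48955500	C	T	RB1	995	0	1005	0	1005	0	1012	160
chr2	25234373	C	T	DNMT3A	1002	498	1000	489	1004	452	998	441
chr5	1295228	G	A	TERT	1012	0	1022	19	1030	340	1008	298
chr5	67591246	A	G	PIK3R1	1000	0	1005	0	1015	275	1003	251
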