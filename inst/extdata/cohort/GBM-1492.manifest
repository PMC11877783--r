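patient_id=GBM-1492
table=GBM-1492.variants.tsv
blood=GBM-1492_B
svz=GBM-1492_SVZ
primary=GBM-1492_P
recurrent=GBM-1492_R
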