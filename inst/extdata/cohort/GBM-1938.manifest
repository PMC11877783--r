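patient_id=GBM-1938
table=GBM-1938.variants.tsv
blood=GBM-1938_B
svz=GBM-1938_SVZ
primary=GBM-1938_P
recurrent=GBM-1938_R
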