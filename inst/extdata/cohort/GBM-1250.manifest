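patient_id=GBM-1250
table=GBM-1250.variants.tsv
blood=GBM-1250_B
svz=GBM-1250_SVZ
primary=GBM-1250_P
recurrent=GBM-1250_R
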