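patient_id=GBM-244
table=GBM-244.variants.tsv
blood=GBM-244_B
svz=GBM-244_SVZ
primary=GBM-244_P
recurrent=GBM-244_R
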