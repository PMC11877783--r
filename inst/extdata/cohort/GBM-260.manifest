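patient_id=GBM-260
table=GBM-260.variants.tsv
blood=GBM-260_B
svz=GBM-260_SVZ
primary=GBM-260_P
recurrent=GBM-260_R
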