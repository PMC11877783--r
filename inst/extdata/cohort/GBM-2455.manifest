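patient_id=GBM-2455
table=GBM-2455.variants.tsv
blood=GBM-2455_B
svz=GBM-2455_SVZ
primary=GBM-2455_P
recurrent=GBM-2455_R
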