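patient_id=GBM-2437
table=GBM-2437.variants.tsv
blood=GBM-2437_B
svz=GBM-2437_SVZ
primary=GBM-2437_P
recurrent=GBM-2437_R
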