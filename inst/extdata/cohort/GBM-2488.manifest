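patient_id=GBM-2488
table=GBM-2488.variants.tsv
blood=GBM-2488_B
svz=GBM-2488_SVZ
primary=GBM-2488_P
recurrent=GBM-2488_R
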