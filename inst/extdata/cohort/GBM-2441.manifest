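patient_id=GBM-2441
table=GBM-2441.variants.tsv
blood=GBM-2441_B
svz=GBM-2441_SVZ
primary=GBM-2441_P
recurrent=GBM-2441_R
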