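patient_id=GBM-1932
table=GBM-1932.variants.tsv
blood=GBM-1932_B
svz=GBM-1932_SVZ
primary=GBM-1932_P
recurrent=GBM-1932_R
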