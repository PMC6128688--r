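genotype,day,value,sd
WT,0,1.000,0.356
WT,1,0.864,0.206
WT,3,5.689,1.076
WT,6,19.802,5.096
KO,0,1.000,0.133
KO,1,1.388,0.077
KO,3,3.518,0.427
KO,6,8.124,1.708
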