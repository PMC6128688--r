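line,genotype,value
HB9,WT,3.487
WT13,WT,2.961
KO5,PZ1KO,3.331
KO6,PZ1KO,3.268
KO8,PZ1KO,3.673
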