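label,sex,n,age_mean,age_sd
ASD,M,33,13.07,2.75
ASD,F,39,13.53,2.58
TD,M,49,13.04,2.68
TD,F,64,12.8125,3.17
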