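feature,count
A,75
V,62
T_mean,12
T_sd,44
MCI,25
K,16
ICI,29
FI,82
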