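variant,peptide,kd_nM,kd_sd_nM
WT,RyR1,256,27
WT,RyR2,110,22
N97I,RyR1,198,38
N97I,RyR2,199,30
Q135P,RyR1,269,39
Q135P,RyR2,317,134
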