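variant,peptide,kd_nM,kd_sd_nM,dh_kcal_mol,dh_sd_kcal_mol,n_titrations
WT,RyR1,12.31,4.87,-9.94,1.23,3
N97I,RyR1,19.93,3.23,-9.58,0.16,3
Q135P,RyR1,62.03,21.13,-19.97,4.37,4
WT,RyR2,8.62,2.20,-11.28,0.62,5
N97I,RyR2,12.32,3.18,-10.02,0.13,3
Q135P,RyR2,83.45,7.99,-16.20,0.14,3
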