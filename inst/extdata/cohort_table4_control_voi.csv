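# Cohort table 4: PSMA-ligand and amino-acid (FET) PET metrics in the
# contralateral control volume of interest. Patient 1 FET fields absent
# (no SUV conversion metadata for that series).
patient,psma_suv_mean,psma_suv_max,fet_suv_mean,fet_suv_max
1,0.04,0.13,NA,NA
2,0.08,0.30,1.28,1.80
3,0.05,0.14,2.51,3.38
4,0.17,0.97,1.32,1.70
5,0.09,0.71,1.50,2.18
6,0.20,2.18,1.45,2.68
7,0.09,1.00,1.12,2.42
8,0.15,1.16,0.82,1.27
9,0.10,0.62,0.96,1.97
10,0.04,0.13,1.35,2.30
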