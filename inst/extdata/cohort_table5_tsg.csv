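# Cohort table 5: PSMA-ligand tumour-to-salivary-gland uptake ratios.
patient,tsg_mean,tsg_max
1,0.32,0.49
2,0.24,0.38
3,0.40,0.36
4,0.09,0.10
5,0.32,0.42
6,0.45,0.46
7,0.15,0.27
8,0.25,0.34
9,0.15,0.31
10,0.16,0.25
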