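# Cohort table 2: PSMA-ligand PET metrics in the biological tumour volume.
patient,volume_mm3,suv_mean,suv_max,tbr_mean,tbr_max
1,59725,1.61,8.09,17.70,81.54
2,17293,2.23,9.18,41.48,208.37
3,5070,0.79,1.96,27.39,112.88
4,4141,1.36,6.17,16.33,40.58
5,37061,1.90,8.55,14.89,67.76
6,95916,1.87,7.09,22.52,101.40
7,30728,1.81,6.67,10.98,41.59
8,2956,1.68,7.28,19.23,70.85
9,83177,1.90,8.35,22.76,98.65
10,9483,1.61,8.09,19.27,84.81
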