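# Cohort table 3: amino-acid (FET) PET metrics in the biological tumour
# volume. Patient 1 SUV fields are absent: the metadata needed for SUV
# conversion was not provided for that series.
patient,volume_mm3,suv_mean,suv_max,tbr_mean,tbr_max
1,39765,NA,NA,2.26,4.86
2,9324,2.71,4.96,2.12,3.89
3,2080,5.36,7.73,2.14,3.08
4,974,2.41,2.76,1.83,2.09
5,14211,2.98,4.87,2.05,3.34
6,47071,3.20,6.44,2.22,4.46
7,33819,2.35,4.44,2.22,4.19
8,1863,1.88,3.25,2.29,3.96
9,69664,2.58,7.27,3.12,8.81
10,28136,3.74,11.57,2.76,8.56
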