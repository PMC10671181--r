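# Cohort table 1: dates of the amino-acid (FET) and PSMA-ligand PET scans
# and the interval between them, for the ten-patient dual-tracer cohort.
patient,fet_scan_date,psma_scan_date,interval_days
1,2018-10-11,2018-10-26,15
2,2021-09-09,2021-09-13,4
3,2018-11-15,2018-11-21,6
4,2018-11-29,2018-12-03,4
5,2018-11-08,2018-11-21,13
6,2020-11-13,2020-11-18,5
7,2020-11-13,2020-11-16,3
8,2019-01-24,2019-01-29,5
9,2019-03-28,2019-04-02,5
10,2021-07-15,2021-07-19,4
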