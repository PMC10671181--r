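# Per-patient voxel-wise Pearson correlation coefficients between the two
# tracers' SUV values inside the overlapping biological tumour volume
# (nine evaluable patients).
r
0.50
0.61
0.48
0.52
0.32
0.59
0.77
0.51
0.30
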