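som_group_pct,peak,wavelength_nm,strength
0.40,1,1451,0.0490
0.40,2,1931,0.1104
0.40,3,2210,0.0417
1.12,1,1447,0.0506
1.12,2,1930,0.1032
1.12,3,2210,0.0428
2.12,1,1449,0.0358
2.12,2,1929,0.0711
2.12,3,2207,0.0290
3.35,1,1445,0.0259
3.35,2,1934,0.0511
3.35,3,2209,0.0209
4.51,1,1447,0.0100
4.51,2,1934,0.0249
4.51,3,2210,0.0078
7.92,1,1447,0.0044
7.92,2,1933,0.0122
7.92,3,2210,0.0034
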