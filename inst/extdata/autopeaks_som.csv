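moisture_group_pct,peak,wavelength_nm,strength
0,1,597,0.0059
0,2,1646,0.0056
5,1,609,0.0034
5,2,1647,0.0069
5,3,2138,0.0054
10,3,2231,0.0085
10,4,1418,0.0107
10,5,1906,0.0112
15,3,2227,0.0218
15,4,1444,0.0262
15,5,1930,0.0371
17,3,2226,0.0299
17,4,1453,0.0346
17,5,1927,0.0494
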