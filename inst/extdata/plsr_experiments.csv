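experiment,n_bands,r2_c,rmsec,r2_cv,rmsecv,r2_p,rmsep,rpd
A,2051,0.93,0.32,0.88,0.46,0.88,0.40,3.04
B,1748,0.92,0.36,0.88,0.45,0.89,0.47,2.89
C,1648,0.92,0.36,0.88,0.45,0.92,0.42,3.19
D,459,0.84,0.49,0.83,0.53,0.89,0.67,2.34
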