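id,bacc_mean,bacc_ppi1,bacc_ppi2,bacc_p,tp,fn,fp,tn,hr,far,dprime,aprime
2,57.7,51.9,63.8,0.007,9,43,0,30,0.17,0.03,0.91,0.79
3,73.8,64.9,81.6,0.0001,35,23,3,27,0.60,0.10,1.54,0.85
4,68.6,60.3,76.3,0.0001,27,31,2,28,0.47,0.07,1.41,0.82
5,63.4,54.8,71.4,0.002,23,36,3,27,0.39,0.01,1.00,0.77
6,80.8,71.9,88.3,0.0001,43,12,4,26,0.78,0.13,1.89,0.89
7,64.3,56.0,72.0,0.0007,21,35,2,28,0.38,0.07,1.18,0.79
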