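id,bacc_mean,bacc_ppi1,bacc_ppi2,bacc_p,tp,fn,fp,tn,hr,far,dprime,aprime
1,85.6,78.3,91.5,0.0001,47,13,1,29,0.78,0.03,2.62,0.93
2,66.6,58.1,74.6,0.02,22,30,2,28,0.42,0.07,1.31,0.81
3,74.7,65.5,82.7,0.0001,38,20,4,26,0.66,0.13,1.51,0.85
4,76.7,67.1,85.1,0.0001,46,12,7,23,0.79,0.23,1.55,0.86
5,66.1,56.3,75.1,0.001,32,27,6,24,0.54,0.20,0.95,0.76
6,79.4,70.1,87.4,0.0001,45,10,6,24,0.82,0.20,1.75,0.88
7,63.7,54.5,72.2,0.003,24,32,4,26,0.43,0.13,0.93,0.76
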