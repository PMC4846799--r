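id,bacc_mean,bacc_mean_avg100,bacc_ppi1,bacc_ppi2,bacc_p,tp,fn,fp,tn,hr,far,dprime,aprime
1,61.5,58.4,48.6,73.5,0.039,21,16,6,13,0.57,0.32,0.65,0.70
2,58,51.2,45.9,69.3,0.093,15,21,5,16,0.42,0.24,0.50,0.67
3,73.1,72.4,61.1,83.0,0.023,26,15,2,14,0.63,0.13,1.49,0.85
4,73.8,67.1,62.2,83.7,0.009,27,13,3,16,0.68,0.16,1.46,0.85
5,76.3,75.0,67.3,84.4,0.0002,23,17,0,19,0.58,0.05,1.86,0.89
6,81.1,78.8,70.9,89.4,0.0001,27,10,1,18,0.73,0.05,2.23,0.91
7,64.8,62.6,52.9,75.6,0.009,21,19,4,16,0.53,0.20,0.90,0.76
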