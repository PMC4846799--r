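id,avg_altitude_m,avg_airspeed_kmh,avg_airspeed_mps,descent_rate_mean_mps,descent_rate_greatest_mps,rt_improvement_ms,altitude_savings_mean_dr_m,altitude_savings_greatest_dr_m
1,81.4,1122,311.6,69.1,87.4,75,5.2,6.5
2,79.8,1082,300.7,65.4,94.7,67,4.4,6.3
3,80.2,1117,310.3,56.2,83.7,49,2.8,4.1
4,79.8,1115,309.8,79.7,103.2,83,6.6,8.6
5,82.4,1117,310.2,71.8,124.6,58,4.2,7.2
6,82,1122,311.7,75.4,111,139,10.5,15.4
7,79.9,1113,309.1,69.6,93.3,36,2.5,3.4
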