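id,n,tp,fp,org_mean_ms,org_se_ms,bci_mean_ms,bci_se_ms,rt_diff_mean_ms,rt_diff_se_ms,perm_rt_diff_mean_ms,perm_p
1,60,47,1,357.9,5.2,283.1,9.8,74.8,7.8,5.2,0.002
2,52,22,2,436.5,13.8,369.7,15.6,66.7,14.3,6.4,0.023
3,58,38,4,454.0,10.2,405.2,13.6,48.7,7.9,4.5,0.014
4,58,46,7,359.8,7.3,277.0,10.6,82.8,10.4,4.9,0.001
5,59,32,6,462.2,6.6,404.2,12.7,58.0,11.8,3.1,0.003
6,55,45,6,480.4,7.3,341.4,14.1,138.9,15.4,13.5,0.002
7,56,24,4,424.1,9.3,388.0,13.3,36.1,8.6,7.4,0.041
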