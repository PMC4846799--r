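id,n,tp,fp,org_mean_ms,org_se_ms,bci_mean_ms,bci_se_ms,rt_diff_mean_ms,rt_diff_se_ms,perm_rt_diff_mean_ms,perm_p
2,52,9,0,436.5,13.8,408.7,15.6,27.8,10.7,7.9,0.026
3,58,35,3,454.0,10.2,407.3,13.5,46.7,7.7,5.5,0.009
4,58,27,2,359.8,7.3,327.9,9.3,31.9,7.9,4.1,0.001
5,59,23,3,462.2,6.6,427.7,11.2,34.5,9.5,2.9,0.001
6,55,43,4,480.4,7.3,347.9,15.8,132.5,15.7,17.8,0.002
7,56,21,2,424.1,9.3,388.7,11.8,35.4,9.2,2.8,0.006
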