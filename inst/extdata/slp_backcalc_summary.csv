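nominal,level_name,mean,sd,rsd_pct,accuracy_pct,recovery_pct
1,LLQC,0.95,0.02,2.08,-5.08,94.92
3,LQC,3.09,0.03,1.00,3.15,103.15
15,,15.16,0.19,1.28,1.07,101.07
50,,50.98,1.10,2.15,1.97,101.97
100,,105.06,1.47,1.40,5.06,105.06
300,,303.45,2.36,0.78,1.15,101.15
500,,502.91,1.41,0.28,0.58,100.58
900,MQC,898.67,4.33,0.48,-0.15,99.85
1500,,1492.58,11.37,0.76,-0.49,99.51
2400,HQC,2387.68,34.32,1.44,-0.51,99.49
3000,,3025.03,36.16,1.20,0.83,100.83
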