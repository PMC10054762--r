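level_name,nominal,scope,mean,sd,precision_rsd_pct,accuracy_pct,recovery_pct
LLQC,1,intra_batch,0.95,0.02,2.08,-5.08,94.92
LQC,3,intra_batch,3.09,0.03,1.00,3.15,103.15
MQC,900,intra_batch,898.67,4.33,0.48,-0.15,99.85
HQC,2400,intra_batch,2387.68,34.32,1.44,-0.51,99.49
LLQC,1,inter_batch,0.93,0.02,2.01,-6.56,93.44
LQC,3,inter_batch,3.16,0.10,3.08,5.22,105.22
MQC,900,inter_batch,912.08,15.59,1.71,1.34,101.34
HQC,2400,inter_batch,2375.59,24.66,1.04,-1.02,98.98
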