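time_min,conc,replicate_id
0,626,1
2.5,586,1
7.5,527,1
15,418,1
20,353,1
30,264,1
40,238,1
50,227,1
60,218,1
70,197,1
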