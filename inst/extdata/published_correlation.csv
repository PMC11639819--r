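parameter,weight_kg,bmi,tbw_kg,ffm_kg,bf_pct,mm_kg,bm_kg
weight_kg,1.000,0.241,0.161,0.277,0.437,0.160,-0.007
bmi,0.241,1.000,0.296,-0.047,0.827,0.175,0.201
tbw_kg,0.161,0.296,1.000,0.132,0.319,-0.002,-0.011
ffm_kg,0.277,-0.047,0.132,1.000,0.438,0.527,0.166
bf_pct,0.437,0.827,0.319,0.438,1.000,0.444,0.382
mm_kg,0.160,0.175,-0.002,0.527,0.444,1.000,0.030
bm_kg,-0.007,0.201,-0.011,0.166,0.382,0.030,1.000
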