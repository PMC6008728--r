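temp_C,kex_s1,kex_sigma_s1,pE_pct,pE_sigma_pct
1.0,649,50,4.7,0.2
5.3,1099,57,4.7,0.2
10.4,2240,122,3.8,0.5
15.4,3871,79,3.5,0.2
20.4,6100,350,3.6,0.6
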