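age_lo,age_hi,mu_lf,sigma_lf
20,25,-0.04999999999999999,0.5
25,30,-0.14999999999999997,0.5
30,35,-0.25,0.5
35,40,-0.35,0.5
40,45,-0.45,0.5
45,50,-0.55,0.5
50,55,-0.65,0.5
55,60,-0.75,0.5
60,65,-0.8500000000000001,0.5
65,70,-0.95,0.5
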