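lower,upper,n
0,200,70
200,400,284
400,600,377
600,800,358
800,1000,288
1000,1200,241
1200,1400,134
1400,1600,77
1600,1800,40
1800,5400,65
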