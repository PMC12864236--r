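grade,weight
1,0.110
2,0.260
3,0.370
4,0.600
5,0.790
6,1.000
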