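a_um,delta0_ms
1,0
2,0
3,0
4,0
5,0
6,1.9
7,3.8
8,5.8
9,9.2
10,11.6
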