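i,j,rho
1,2,0.5
1,7,0.5
3,4,-0.5
3,5,-0.3
4,5,0.5
4,7,0.3
4,8,0.5
4,9,0.3
5,8,0.3
5,9,0.3
6,7,-0.3
6,8,0.3
8,9,0.5
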