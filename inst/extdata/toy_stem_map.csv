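x,y,species
0.1,0.1,A
0.6,0.6,A
0.1,0.6,B
0.9,0.2,C
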