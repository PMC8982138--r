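id,A,B,C,D,E
s1,100,0,0,0,0
s2,80,20,0,0,0
s3,90,0,10,0,0
s4,100,0,0,0,0
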