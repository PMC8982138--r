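id,A,B,C
s1,5,10,15
s2,2,3,5
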