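id,A,B
s1,10,20
s2,2,3
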