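id,A,B
s1,200,0
s2,150,40
s3,180,0
s4,220,0
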