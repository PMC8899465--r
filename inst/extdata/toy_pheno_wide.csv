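subject,t1,t2,t3
s1,1.1,1.4,1.9
s2,0.8,1.2,1.5
s3,1.0,1.1,1.3
s4,1.3,,1.8
s5,0.9,1.0,1.2
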